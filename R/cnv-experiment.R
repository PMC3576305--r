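#' Build a CNVExperiment from a copy-number matrix
#'
#' @param copies integer matrix of copy-number calls (values 0-6 or `NA`),
#'   loci in rows and individuals in columns.  Rownames are the locus ids;
#'   generated as `locus1, locus2, ...` when absent.
#' @param group per-individual group label (factor or coercible); levels are
#'   kept in first-appearance order.
#' @param covariate optional per-individual categorical covariate.
#'
#' @return A [CNVExperiment-class].
#' @examples
#' x <- matrix(c(2L, 2L, 1L, 2L, 0L, 2L), nrow = 2,
#'             dimnames = list(c("cnvA", "cnvB"), NULL))
#' ce <- CNVExperiment(x, group = c("ctrl", "case", "case"))
#' groupLabels(ce)
#' @export
CNVExperiment <- function(copies, group, covariate = NULL) {
  copies <- as.matrix(copies)
  if (is.null(rownames(copies)))
    rownames(copies) <- paste0("locus", seq_len(nrow(copies)))
  storage.mode(copies) <- "integer"
  if (length(group) != ncol(copies))
    stop("length(group) must equal the number of individuals (columns)")
  cd <- S4Vectors::DataFrame(group = .firstAppearanceFactor(group))
  if (!is.null(covariate)) {
    if (length(covariate) != ncol(copies))
      stop("length(covariate) must equal the number of individuals")
    cd$covariate <- .firstAppearanceFactor(covariate)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(copies = copies), colData = cd)
  new("CNVExperiment", se)
}

.firstAppearanceFactor <- function(x) factor(x, levels = unique(as.character(x)))

#' @describeIn CNVExperiment the loci x individuals copy matrix.
#' @param object,x a `CNVExperiment`.
#' @export
copyNumbers <- function(x) SummarizedExperiment::assay(x, "copies")

#' @describeIn CNVExperiment per-individual group labels (factor).
#' @export
groupLabels <- function(x) SummarizedExperiment::colData(x)$group

#' @describeIn CNVExperiment per-individual covariate labels, or `NULL`.
#' @export
covariateLabels <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("covariate" %in% colnames(cd)) cd$covariate else NULL
}

#' @describeIn CNVExperiment locus identifiers.
#' @export
lociIds <- function(x) rownames(x)

setMethod("show", "CNVExperiment", function(object) {
  g <- groupLabels(object)
  cat("CNVExperiment:", nrow(object), "loci x", ncol(object), "individuals\n")
  cat("groups:", paste(sprintf("%s (%d)", levels(g), tabulate(g)),
                       collapse = ", "), "\n")
  cv <- covariateLabels(object)
  if (!is.null(cv)) cat("covariate levels:", paste(levels(cv), collapse = ", "), "\n")
  nm <- sum(is.na(copyNumbers(object)))
  if (nm > 0) cat("missing calls:", nm, "\n")
})

#' Read a copy-number table
#'
#' Reads a delimited text file with one row per individual: an individual id
#' column, a group-label column, an optional covariate column, then one
#' column per locus (header = locus id) holding integer copy numbers 0-6.
#' Group labels are mapped to levels in first-appearance order.
#'
#' @param path file path; tab-separated unless the extension is `.csv`.
#' @param missingToken string marking a missing call (default `"NA"`).
#' @param idCol,groupCol,covariateCol column names; `covariateCol = NULL`
#'   (default) means no covariate.
#' @return A [CNVExperiment-class] (loci in rows).
#' @export
readCopyNumberTable <- function(path, missingToken = "NA",
                                idCol = "id", groupCol = "group",
                                covariateCol = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c(idCol, groupCol, covariateCol)
  if (!all(need %in% colnames(df)))
    stop("missing column(s): ", paste(setdiff(need, colnames(df)), collapse = ", "))
  lcols <- colnames(df)[!colnames(df) %in% need]
  if (length(lcols) == 0L) stop("no locus columns found")
  if (anyDuplicated(lcols))
    stop("duplicate locus ids: ",
         paste(unique(lcols[duplicated(lcols)]), collapse = ", "))
  raw <- as.matrix(df[, lcols, drop = FALSE])
  raw[raw == missingToken] <- NA_character_
  suppressWarnings(num <- matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(!is.na(raw) & (is.na(num) | num != round(num) | num < 0 | num > 6),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid copy value '%s' at row %d (individual '%s'), locus '%s'",
                 raw[bad[1, 1], bad[1, 2]], bad[1, 1],
                 df[[idCol]][bad[1, 1]], lcols[bad[1, 2]]))
  copies <- t(num)
  rownames(copies) <- lcols
  colnames(copies) <- df[[idCol]]
  CNVExperiment(copies, group = df[[groupCol]],
                covariate = if (is.null(covariateCol)) NULL else df[[covariateCol]])
}

#' Write a copy-number table readable by [readCopyNumberTable()]
#'
#' @param x a [CNVExperiment-class].
#' @param path output file (tab-separated unless it ends in `.csv`).
#' @param missingToken string used for missing calls.
#' @return `path`, invisibly.
#' @export
writeCopyNumberTable <- function(x, path, missingToken = "NA") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  m <- t(copyNumbers(x))
  ids <- colnames(copyNumbers(x))
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(m)))
  df <- data.frame(id = ids, group = as.character(groupLabels(x)),
                   stringsAsFactors = FALSE, check.names = FALSE)
  cv <- covariateLabels(x)
  if (!is.null(cv)) df$covariate <- as.character(cv)
  m2 <- matrix(as.character(m), nrow = nrow(m), dimnames = dimnames(m))
  m2[is.na(m)] <- missingToken
  df <- cbind(df, as.data.frame(m2, check.names = FALSE))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
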