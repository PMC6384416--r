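#' Construct an expression table
#'
#' Holds one row per gene: the log2 fold-change \code{beta} and its variance.
#' Standard errors are accepted and squared. Multiple probes per gene must be
#' collapsed first (see \code{\link{collapse_probes}}); one row per symbol is
#' enforced.
#'
#' @param gene Gene symbols.
#' @param beta log2 fold-changes.
#' @param variance Per-gene variance of beta (>= 0). Give either this or
#'   \code{se}.
#' @param se Standard errors (squared into variance).
#' @return data.frame of class \code{"expression_table"} with columns
#'   \code{gene}, \code{beta}, \code{variance}.
#' @export
expression_table <- function(gene, beta, variance = NULL, se = NULL) {
  gene <- as.character(gene)
  beta <- as.numeric(beta)
  if (is.null(variance)) {
    if (is.null(se)) stop("give either variance or se")
    variance <- as.numeric(se)^2
  }
  if (length(gene) != length(beta) || length(gene) != length(variance))
    stop("gene, beta and variance must have equal length")
  if (any(variance < 0)) stop("variance must be non-negative")
  if (anyDuplicated(gene))
    stop("duplicate gene symbol(s): ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "),
         "; collapse probes first (collapse_probes)")
  out <- data.frame(gene = gene, beta = beta, variance = variance,
                    stringsAsFactors = FALSE)
  class(out) <- c("expression_table", "data.frame")
  out
}

#' Collapse probe-level rows to one row per gene
#'
#' Probe-level fold-changes mapping to the same symbol are averaged; the
#' variance of the mean of n independent probes is mean(variance)/n.
#'
#' @param gene,beta,variance Probe-level vectors (symbols may repeat).
#' @return An \code{"expression_table"}.
#' @export
collapse_probes <- function(gene, beta, variance) {
  gene <- as.character(gene)
  n <- tapply(beta, gene, length)
  b <- tapply(beta, gene, mean)
  v <- tapply(variance, gene, mean) / n
  expression_table(names(b), as.numeric(b), as.numeric(v))
}

#' Read an expression table from TSV/CSV
#'
#' Expects a header with a gene column (\code{gene} or \code{symbol}), a
#' fold-change column (\code{logFC} or \code{beta}) and either \code{SE} or
#' \code{variance}. The delimiter is inferred from the extension
#' (\code{.csv} vs tab-separated otherwise).
#'
#' @param path Input file.
#' @return An \code{"expression_table"}.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(tab))
  gcol <- which(nm %in% c("gene", "symbol"))[1]
  bcol <- which(nm %in% c("logfc", "beta", "log2fc"))[1]
  vcol <- which(nm %in% c("variance", "var"))[1]
  scol <- which(nm %in% c("se", "stderr"))[1]
  if (is.na(gcol) || is.na(bcol) || (is.na(vcol) && is.na(scol)))
    stop("expression file must have columns (gene|symbol), (logFC|beta), ",
         "and (SE|variance): ", path)
  if (!is.na(vcol))
    expression_table(tab[[gcol]], tab[[bcol]], variance = tab[[vcol]])
  else
    expression_table(tab[[gcol]], tab[[bcol]], se = tab[[scol]])
}

#' Write an expression table
#'
#' @param table An \code{"expression_table"}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(table, path) {
  utils::write.table(data.frame(gene = table$gene, logFC = table$beta,
                                variance = table$variance),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
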