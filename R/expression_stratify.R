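# Bulk-transcriptome stratification: RLE (median-of-ratios) CPM
# normalization, median split by a stratification gene, paired-compartment
# Spearman correlation, and the signed -log(p) ranking statistic for
# preranked enrichment.

#' RLE-normalized counts per million
#'
#' Median-of-ratios library-size normalization: the reference is the
#' per-gene geometric mean of count proportions over genes with positive
#' counts in every sample; each sample's raw factor is the median ratio of
#' its proportions to the reference; factors are rescaled to geometric
#' mean 1; and `CPM = count / (library_size * factor) * 1e6`. Genes with a
#' zero in any sample are excluded from the reference only, never from the
#' output.
#'
#' @param counts Non-negative integer matrix, genes x samples, with row
#'   and column names; >= 2 samples and at least one gene positive in all
#'   samples.
#' @return An object of class `cpm_matrix`: a list with `cpm` (genes x
#'   samples), `norm_factors` (geometric mean 1) and `lib_sizes`.
#' @examples
#' m <- matrix(c(10, 20, 30, 30, 60, 90), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("A", "B")))
#' rle_cpm(m)$norm_factors  # B is a scaled copy of A: factors are 1, 1
#' @export
rle_cpm <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need >= 2 samples", call. = FALSE)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "), call. = FALSE)
  }
  prop <- sweep(counts, 2, lib, "/")
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    stop("no gene has positive counts in every sample: RLE reference undefined",
         call. = FALSE)
  }
  ref <- exp(rowMeans(log(prop[all_pos, , drop = FALSE])))
  f_raw <- apply(prop[all_pos, , drop = FALSE], 2,
                 function(p) median(p / ref))
  f <- f_raw / exp(mean(log(f_raw)))
  cpm <- sweep(counts, 2, lib * f, "/") * 1e6
  structure(list(cpm = cpm, norm_factors = f, lib_sizes = lib),
            class = "cpm_matrix")
}

#' @export
print.cpm_matrix <- function(x, ...) {
  cat(sprintf("<cpm_matrix> %d genes x %d samples (RLE-normalized CPM)\n",
              nrow(x$cpm), ncol(x$cpm)))
  cat("  factors: ", paste(format(x$norm_factors, digits = 3), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Median split of samples by one gene's CPM
#'
#' Restricts the gene's CPM row to `samples` (e.g. the stroma compartment)
#' and dichotomizes at the median via [dichotomize_by_median()], yielding
#' the gene-high / gene-low cohort labels.
#'
#' @param cpm A [rle_cpm()] result.
#' @param gene_id Row name of the stratification gene.
#' @param samples Optional character vector of sample (column) names;
#'   default all samples.
#' @param ties Tie side passed to [dichotomize_by_median()].
#' @return A `dichotomy_labels` object keyed by sample name.
#' @export
median_split_by_gene <- function(cpm, gene_id, samples = NULL,
                                 ties = c("low", "high")) {
  if (!gene_id %in% rownames(cpm$cpm)) {
    stop("gene not in matrix: ", gene_id, call. = FALSE)
  }
  vals <- cpm$cpm[gene_id, ]
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, names(vals))
    if (length(missing_s) > 0) {
      stop("unknown sample(s): ", paste(missing_s, collapse = ", "),
           call. = FALSE)
    }
    vals <- vals[samples]
  }
  if (length(vals) < 2) stop("need >= 2 samples in subset", call. = FALSE)
  dichotomize_by_median(unname(vals), ids = names(vals),
                        ties = match.arg(ties))
}

#' Paired epithelium-stroma Spearman correlation of one gene
#'
#' Correlates a gene's log2(CPM + pseudocount) between the two
#' compartments of each subject. Subjects lacking either compartment are
#' dropped and reported. Spearman rho uses midranks; the two-tailed p
#' value comes from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#' Being rank-based, the result is invariant to the pseudocount and to any
#' strictly increasing per-axis transform.
#'
#' @param cpm A [rle_cpm()] result.
#' @param gene_id Gene (row) name.
#' @param annotation Data frame with columns `sample`, `subject`,
#'   `compartment` (values `epithelium` / `stroma`).
#' @param pseudocount Offset inside the log (default 1).
#' @return A list with `rho`, `p_two_tailed`, `n_pairs`,
#'   `dropped_subjects`.
#' @export
paired_spearman <- function(cpm, gene_id, annotation, pseudocount = 1) {
  if (!gene_id %in% rownames(cpm$cpm)) {
    stop("gene not in matrix: ", gene_id, call. = FALSE)
  }
  need <- c("sample", "subject", "compartment")
  if (!all(need %in% names(annotation))) {
    stop("annotation needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  vals <- log2(cpm$cpm[gene_id, ] + pseudocount)
  ann <- annotation[annotation$sample %in% names(vals), , drop = FALSE]
  get_val <- function(subj, comp) {
    s <- ann$sample[ann$subject == subj & ann$compartment == comp]
    if (length(s) == 1) vals[[s]] else NA_real_
  }
  subjects <- unique(ann$subject)
  e <- vapply(subjects, get_val, 0, comp = "epithelium")
  s <- vapply(subjects, get_val, 0, comp = "stroma")
  complete <- !is.na(e) & !is.na(s)
  dropped <- subjects[!complete]
  n <- sum(complete)
  if (n < 3) stop("fewer than 3 complete epithelium-stroma pairs",
                  call. = FALSE)
  rho <- cor(rank(e[complete]), rank(s[complete]))
  if (1 - rho^2 < .Machine$double.eps) {
    p <- 0  # |rho| = 1: t statistic diverges
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_two_tailed = p, n_pairs = n,
       dropped_subjects = as.character(dropped))
}

#' Signed -log(p) ranking statistic for preranked enrichment
#'
#' Per gene, `rank_stat = -ln(p) * sign(log2FC)`; the output is sorted in
#' decreasing order with ties broken lexicographically by gene id. The
#' differential-expression fit producing `log2FC` and `p` is consumed as
#' input, not computed here. The log base only scales the statistic and
#' never changes the ordering; natural log is used.
#'
#' @param de Data frame with columns `gene`, `log2FC`, `pvalue`
#'   (p in (0, 1]; zero p must be floored by the caller).
#' @return Data frame `gene`, `rank_stat`, sorted for `.rnk` output.
#' @examples
#' rank_statistic(data.frame(gene = c("a", "b"),
#'                           log2FC = c(-2, 1), pvalue = c(0.01, 0.5)))
#' @export
rank_statistic <- function(de) {
  need <- c("gene", "log2FC", "pvalue")
  if (!all(need %in% names(de))) {
    stop("DE table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(de$pvalue <= 0)) {
    stop("p = 0 (or negative) found: the statistic is undefined; ",
         "floor p values first", call. = FALSE)
  }
  if (any(de$pvalue > 1) || any(!is.finite(de$log2FC))) {
    stop("p values must lie in (0, 1] and log2FC must be finite",
         call. = FALSE)
  }
  stat <- -log(de$pvalue) * sign(de$log2FC)
  out <- data.frame(gene = as.character(de$gene), rank_stat = stat,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$rank_stat, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a ranking as a two-column .rnk TSV
#'
#' @param ranking Output of [rank_statistic()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_rnk <- function(ranking, path) {
  write.table(ranking, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a counts TSV / sample annotation CSV / DE table TSV
#'
#' `read_counts_tsv()` expects gene rows x sample columns with gene ids in
#' the first column; `read_annotation_csv()` expects columns `sample`,
#' `subject`, `compartment`; `read_de_tsv()` expects columns `gene`,
#' `log2FC`, `pvalue`.
#'
#' @param path Input path.
#' @return A counts matrix / data frame.
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m
}

#' @rdname read_counts_tsv
#' @export
read_annotation_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_counts_tsv
#' @export
read_de_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
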