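#' Simulate a paired-compartment negative-binomial count cohort
#'
#' Emulates a laser-capture-microdissection RNA-seq design: each subject
#' contributes one epithelium and one stroma library. Gene baselines are
#' log-normal, counts are negative binomial with a common dispersion, and
#' per-sample depth factors are log-normal so that library-size
#' normalization has real work to do. A designated stratification gene is
#' bimodal in the stroma: each subject's stroma belongs to a high or low
#' expression component (fold difference `strat_fold`), while its
#' epithelial expression is drawn independently — so compartments are
#' uncorrelated for that gene by construction. Component membership is
#' balanced exactly (`round(n_subjects * p_high)` subjects high, chosen by
#' random permutation), emulating a cohort genuinely stratified by the
#' designated gene rather than one with binomially fluctuating component
#' sizes.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_subjects Number of subjects, each with two samples (default
#'   65, a cohort size typical of microdissected series).
#' @param strat_gene Name given to the stratification gene (default
#'   `"GRN"`).
#' @param strat_fold Fold change between the stroma components (default 4).
#' @param p_high Probability a subject's stroma is in the high component.
#' @param base_log_mean,base_log_sd Meanlog / sdlog of the per-gene
#'   baseline expression.
#' @param dispersion Negative-binomial dispersion (1 / size).
#' @param depth_log_sd Sdlog of the per-sample depth factor.
#' @param seed Integer RNG seed.
#' @return A list with `counts` (genes x samples integer matrix),
#'   `annotation` (data frame `sample`, `subject`, `compartment`) and
#'   `truth` (data frame `subject`, `stroma_component` in
#'   `high` / `low`).
#' @examples
#' sim <- simulate_counts(n_genes = 200, n_subjects = 10, seed = 1)
#' dim(sim$counts)
#' @export
simulate_counts <- function(n_genes = 2000, n_subjects = 65,
                            strat_gene = "GRN", strat_fold = 4,
                            p_high = 0.5,
                            base_log_mean = 4, base_log_sd = 1.2,
                            dispersion = 0.1, depth_log_sd = 0.3,
                            seed = 1L) {
  if (n_genes < 2 || n_subjects < 2) {
    stop("need >= 2 genes and >= 2 subjects", call. = FALSE)
  }
  if (strat_fold <= 0 || dispersion <= 0) {
    stop("`strat_fold` and `dispersion` must be positive", call. = FALSE)
  }
  streams <- rng_substreams(seed, 4L)
  names(streams) <- c("genes", "components", "depth", "counts")

  base_mu <- with_stream(streams$genes,
                         rlnorm(n_genes, base_log_mean, base_log_sd))
  genes <- c(strat_gene,
             sprintf("gene%0*d", nchar(n_genes), seq_len(n_genes - 1L)))

  n_high <- round(n_subjects * p_high)
  comps <- with_stream(streams$components, {
    pick <- function() {
      out <- logical(n_subjects)
      out[sample(n_subjects, n_high)] <- TRUE
      out
    }
    # stroma component, then an independent epithelial status
    list(stroma = pick(), epi = pick())
  })
  comp_high <- comps$stroma
  epi_high <- comps$epi

  samples <- c(sprintf("S%02d_epi", seq_len(n_subjects)),
               sprintf("S%02d_str", seq_len(n_subjects)))
  n_samp <- 2L * n_subjects
  depth <- with_stream(streams$depth, rlnorm(n_samp, 0, depth_log_sd))

  mu <- matrix(base_mu, nrow = n_genes, ncol = n_samp)
  # stratification gene sits in row 1; low component = baseline,
  # high component = baseline * strat_fold
  mu[1, n_subjects + which(comp_high)] <-
    mu[1, n_subjects + which(comp_high)] * strat_fold
  mu[1, which(epi_high)] <- mu[1, which(epi_high)] * strat_fold
  mu <- sweep(mu, 2, depth, "*")

  counts <- with_stream(streams$counts, {
    matrix(rnbinom(n_genes * n_samp, mu = as.vector(mu),
                   size = 1 / dispersion),
           nrow = n_genes, ncol = n_samp)
  })
  dimnames(counts) <- list(genes, samples)

  annotation <- data.frame(
    sample = samples,
    subject = rep(sprintf("S%02d", seq_len(n_subjects)), 2),
    compartment = rep(c("epithelium", "stroma"), each = n_subjects),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    subject = sprintf("S%02d", seq_len(n_subjects)),
    stroma_component = ifelse(comp_high, "high", "low"),
    stringsAsFactors = FALSE)

  list(counts = counts, annotation = annotation, truth = truth)
}
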