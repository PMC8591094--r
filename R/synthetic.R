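# Seeded generators emulating every pipeline input, with known ground
# truth: a two-class expression matrix with planted differential genes, a
# planted-partition interaction graph whose blocks concentrate the
# differential genes, a copy-number gene list overlapping the truth, and
# exponential proportional-hazards survival driven by a supplied risk.

#' Specification for the synthetic generators
#'
#' Defaults emulate a desk-scale two-class microarray study: 500 genes on
#' a 35-tumor / 24-normal design, 10% truly differential genes at a log2
#' effect of 2.0 with residual noise SD 0.5, a 5-block planted-partition
#' interaction graph (8 nodes per block, within-block edge probability
#' 0.6, between-block 0.05), half of the true differential genes carrying
#' copy-number alterations, and exponential survival with a unit
#' log-hazard coefficient on the standardized risk and 20% censoring.
#'
#' @param n_genes Number of genes.
#' @param n_case,n_control Samples per class.
#' @param de_fraction Fraction of genes truly differential, in (0, 1).
#' @param effect_log2 Log2 shift applied to true differential genes in
#'   cases.
#' @param noise_sd Residual noise standard deviation (log2 units), > 0.
#' @param n_blocks,block_size Planted-partition structure
#'   (`n_blocks * block_size <= n_genes`).
#' @param p_in,p_out Within/between-block edge probabilities
#'   (`p_in > p_out` for planted structure).
#' @param seed_overlap_fraction Fraction of true differential genes present
#'   in the copy-number list.
#' @param survival_beta Log-hazard coefficient on the standardized risk.
#' @param baseline_hazard Baseline exponential hazard rate, > 0.
#' @param censor_rate Target censoring fraction, in \[0, 1).
#' @param rng_seed Integer RNG seed; all generators are bitwise
#'   reproducible for a fixed seed.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 500L, n_case = 35L, n_control = 24L,
                           de_fraction = 0.1, effect_log2 = 2.0,
                           noise_sd = 0.5, n_blocks = 5L, block_size = 8L,
                           p_in = 0.6, p_out = 0.05,
                           seed_overlap_fraction = 0.5,
                           survival_beta = 1.0, baseline_hazard = 0.1,
                           censor_rate = 0.2, rng_seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes), n_case = as.integer(n_case),
               n_control = as.integer(n_control),
               de_fraction = de_fraction, effect_log2 = effect_log2,
               noise_sd = noise_sd, n_blocks = as.integer(n_blocks),
               block_size = as.integer(block_size), p_in = p_in,
               p_out = p_out, seed_overlap_fraction = seed_overlap_fraction,
               survival_beta = survival_beta,
               baseline_hazard = baseline_hazard, censor_rate = censor_rate,
               rng_seed = as.integer(rng_seed))
  stopifnot(spec$n_genes >= 1L, spec$n_case >= 2L, spec$n_control >= 2L,
            spec$de_fraction > 0, spec$de_fraction < 1,
            spec$noise_sd > 0, spec$n_blocks >= 1L, spec$block_size >= 1L,
            spec$p_in >= 0, spec$p_in <= 1, spec$p_out >= 0, spec$p_out <= 1,
            spec$seed_overlap_fraction >= 0, spec$seed_overlap_fraction <= 1,
            spec$baseline_hazard > 0,
            spec$censor_rate >= 0, spec$censor_rate < 1)
  if (spec$n_blocks * spec$block_size > spec$n_genes)
    stopf("n_blocks * block_size exceeds n_genes")
  structure(spec, class = "synthetic_spec")
}

#' Generate a two-class expression matrix with planted differential genes
#'
#' Baseline per-gene log2 intensities are drawn from Normal(7, 1). A
#' fraction `de_fraction` of genes is truly differential: shifted by
#' `± effect_log2` in cases (sign random, recorded). I.i.d.
#' Normal(0, `noise_sd`) noise is added everywhere and class labels are
#' attached.
#'
#' @param spec A [synthetic_spec()].
#' @param de_truth Optional frozen truth (the `de_truth` of a previous
#'   call) so an independent validation cohort shares the same ground
#'   truth; by default a fresh truth is drawn.
#' @param cohort Tag prefixed to sample ids, so cohorts generated from the
#'   same spec have distinct sample names.
#' @return List with `expr` (an [expression_matrix()]) and `de_truth`
#'   (data.frame: gene, sign, is_de for the planted genes).
#' @export
gen_expression <- function(spec, de_truth = NULL, cohort = "train") {
  with_seed(stage_seed(spec$rng_seed, paste0("expr_", cohort)), {
    genes <- sprintf("G%04d", seq_len(spec$n_genes))
    if (is.null(de_truth)) {
      n_de <- round(spec$de_fraction * spec$n_genes)
      if (n_de < 1L) {
        warnf("de_fraction * n_genes < 1: no differential genes planted")
        de_genes <- character(0); signs <- numeric(0)
      } else {
        de_genes <- sort(sample(genes, n_de))
        signs <- sample(c(-1, 1), n_de, replace = TRUE)
      }
      de_truth <- data.frame(gene = de_genes, sign = signs,
                             stringsAsFactors = FALSE)
    }
    samples <- c(sprintf("%s_case_%02d", cohort, seq_len(spec$n_case)),
                 sprintf("%s_ctrl_%02d", cohort, seq_len(spec$n_control)))
    labels <- stats::setNames(rep(c("case", "control"),
                                  c(spec$n_case, spec$n_control)), samples)
    baseline <- stats::rnorm(spec$n_genes, mean = 7, sd = 1)
    vals <- matrix(baseline, spec$n_genes, length(samples)) +
      matrix(stats::rnorm(spec$n_genes * length(samples), 0, spec$noise_sd),
             spec$n_genes, length(samples))
    dimnames(vals) <- list(genes, samples)
    if (nrow(de_truth)) {
      idx <- match(de_truth$gene, genes)
      vals[idx, seq_len(spec$n_case)] <-
        vals[idx, seq_len(spec$n_case)] + de_truth$sign * spec$effect_log2
    }
    list(expr = expression_matrix(vals, labels), de_truth = de_truth)
  })
}

#' Generate a planted-partition interaction graph and copy-number list
#'
#' Assigns `n_blocks * block_size` genes to blocks — true differential
#' genes first, so the planted marker blocks are enriched for them — and
#' draws each within-block edge with probability `p_in` and each
#' between-block edge with probability `p_out`. The copy-number gene list
#' is a `seed_overlap_fraction` sample of the true differential genes plus
#' an equal number of non-differential decoys, so the seed intersection
#' lands inside the planted blocks.
#'
#' @param spec A [synthetic_spec()].
#' @param de_truth `de_truth` from [gen_expression()] (may be `NULL` for a
#'   pure graph, in which case blocks are filled in gene order and the
#'   copy-number list is empty).
#' @return List with `edges` (two-column character matrix), `blocks`
#'   (named integer vector, gene -> block), `cna_genes` (character).
#' @export
gen_ppi <- function(spec, de_truth = NULL) {
  with_seed(stage_seed(spec$rng_seed, "ppi"), {
    genes <- sprintf("G%04d", seq_len(spec$n_genes))
    n_nodes <- spec$n_blocks * spec$block_size
    de_genes <- if (!is.null(de_truth)) de_truth$gene else character(0)
    nodes <- c(de_genes, setdiff(genes, de_genes))[seq_len(n_nodes)]
    blocks <- stats::setNames(rep(seq_len(spec$n_blocks),
                                  each = spec$block_size), nodes)
    pairs <- utils::combn(nodes, 2)
    same <- blocks[pairs[1, ]] == blocks[pairs[2, ]]
    prob <- ifelse(same, spec$p_in, spec$p_out)
    keep <- stats::runif(length(prob)) < prob
    edges <- cbind(from = pairs[1, keep], to = pairs[2, keep])
    cna_genes <- character(0)
    if (length(de_genes)) {
      n_overlap <- round(spec$seed_overlap_fraction * length(de_genes))
      overlap <- if (n_overlap >= 1L) sort(sample(de_genes, n_overlap))
                 else character(0)
      non_de <- setdiff(genes, de_genes)
      decoys <- sort(sample(non_de, min(length(overlap), length(non_de))))
      cna_genes <- sort(unique(c(overlap, decoys)))
    }
    list(edges = edges, blocks = blocks, cna_genes = cna_genes)
  })
}

#' Generate clinical survival data from a risk vector
#'
#' Event times are exponential with per-sample hazard
#' `baseline_hazard * exp(survival_beta * z)` where `z` is the
#' standardized risk. Censoring is independent Uniform(0, a) with `a`
#' solved numerically so the expected censoring fraction matches
#' `censor_rate` (no censoring when `censor_rate = 0`). Clinical
#' covariates are drawn independently: P(age >= 50) = 0.7,
#' P(female) = 0.5, P(stage III-IV) = 0.5, lymphatic invasion
#' yes/no/unknown with probabilities 0.4/0.5/0.1.
#'
#' @param risk Named numeric vector of per-sample risk values (finite).
#' @param spec A [synthetic_spec()].
#' @return A [clinical_table()] for the risk-named samples.
#' @export
gen_survival <- function(risk, spec) {
  if (!all(is.finite(risk))) stopf("risk values must be finite")
  if (is.null(names(risk))) names(risk) <- sprintf("S%03d", seq_along(risk))
  with_seed(stage_seed(spec$rng_seed, "survival"), {
    z <- if (stats::sd(risk) > 0) as.numeric(scale(risk)) else risk * 0
    lambda <- spec$baseline_hazard * exp(spec$survival_beta * z)
    t_event <- stats::rexp(length(risk), rate = lambda)
    if (spec$censor_rate > 0) {
      # P(censored | C ~ U(0,a)) averaged over samples, solved for a
      pc <- function(a) mean((1 - exp(-lambda * a)) / (lambda * a)) -
        spec$censor_rate
      hi <- 1 / min(lambda)
      while (pc(hi) > 0) hi <- hi * 2
      a <- stats::uniroot(pc, c(1e-8, hi))$root
      t_cens <- stats::runif(length(risk), 0, a)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1L, length(risk))
    }
    n <- length(risk)
    lym <- sample(c("yes", "no", NA_character_), n, replace = TRUE,
                  prob = c(0.4, 0.5, 0.1))
    clinical_table(
      sample = names(risk), time = time, event = event,
      age_group = sample(c(">=50", "<50"), n, TRUE, prob = c(0.7, 0.3)),
      gender = sample(c("female", "male"), n, TRUE),
      stage_group = sample(c("III-IV", "I-II"), n, TRUE),
      lymphatic_invasion = lym)
  })
}
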