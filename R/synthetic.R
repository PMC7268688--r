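#' Default mean regional volumes (mm^3)
#'
#' Order-of-magnitude plausible neonatal grey-matter volumes, identical for
#' the two hemispheres of each structure.  These constants are deliberately
#' round and make no claim of matching real neonatal volumetry; they exist so
#' that synthetic cohorts live on a realistic scale.
#'
#' @param atlas region atlas.
#' @return named numeric vector of 64 mean volumes in atlas order.
#' @export
default_region_means <- function(atlas = load_region_atlas()) {
  base <- c(
    "Thalamus" = 4200, "Putamen" = 1600, "Globus pallidus" = 600,
    "Caudate nucleus" = 1500, "Superior frontal gyrus" = 7500,
    "Middle frontal gyrus" = 6500, "Inferior frontal gyrus" = 4500,
    "Medial fronto-orbital gyrus" = 2200,
    "Lateral fronto-orbital gyrus" = 1800, "Gyrus rectus" = 1200,
    "Precentral gyrus" = 5200, "Postcentral gyrus" = 4800,
    "Superior parietal gyrus" = 4200, "Precuneus" = 3800,
    "Cingular gyrus" = 4600, "Supramarginal gyrus" = 3200,
    "Angular gyrus" = 3000, "Superior temporal gyrus" = 4800,
    "Middle temporal gyrus" = 4400, "Inferior temporal gyrus" = 3600,
    "Fusiform gyrus" = 3400, "Parahippocampal gyrus" = 1700,
    "Entorhinal cortex" = 900, "Superior occipital gyrus" = 2400,
    "Middle occipital gyrus" = 3200, "Inferior occipital gyrus" = 2200,
    "Cuneus" = 2600, "Lingual gyrus" = 3000, "Amygdala" = 550,
    "Hippocampus" = 1300, "Cerebellar hemisphere" = 9500,
    "Insular cortex" = 2600)
  means <- unname(base[atlas$name])
  names(means) <- region_labels(atlas)
  means
}

#' Default skull-stripping workflow biases
#'
#' Multiplicative per-region volume biases emulating the systematic effects
#' of three skull-stripping workflows:
#' \describe{
#'   \item{BET}{0.95 on all cortical and cerebellar regions (deep grey nuclei,
#'     atlas indices 1-8, are left unbiased): an aggressive automatic brain
#'     extraction that truncates peripheral tissue, so most volumes shrink.}
#'   \item{iBEAT}{1.05 on skull-base-adjacent regions (inferior temporal,
#'     fusiform, parahippocampal and entorhinal cortex, cerebellar
#'     hemispheres): residual unremoved tissue at the skull base inflates
#'     nearby volumes.}
#'   \item{iBEAT_corrected}{1 everywhere: the manually corrected workflow is
#'     the unbiased reference.}
#' }
#'
#' @param atlas region atlas.
#' @return named list of three bias vectors of length 64.
#' @export
default_workflow_bias <- function(atlas = load_region_atlas()) {
  labels <- region_labels(atlas)
  bet <- rep(0.95, 64)
  bet[1:8] <- 1            # deep grey nuclei unaffected by stripping errors
  ibeat <- rep(1, 64)
  skull_base <- c(39:46, 61, 62)  # inf. temporal, fusiform, parahippocampal,
                                  # entorhinal, cerebellum
  ibeat[skull_base] <- 1.05
  corrected <- rep(1, 64)
  out <- list(BET = bet, iBEAT = ibeat, iBEAT_corrected = corrected)
  lapply(out, function(b) { names(b) <- labels; b })
}

#' Configuration for synthetic cohort generation
#'
#' Defines the generative model for synthetic volume cohorts: log-volumes
#' are multivariate Gaussian with an exchangeable block (module) correlation
#' structure, so volumes are strictly positive, biases act multiplicatively,
#' and the covariance network constructed from the cohort inherits the
#' module (community) structure that makes it small-world.
#'
#' @param n_subjects number of subjects (default 22).
#' @param seed integer seed; all sampling for a cohort flows from it.
#' @param n_modules number of correlation modules (contiguous blocks of
#'   regions in atlas order).
#' @param within_module_corr log-scale correlation between regions in the
#'   same module.
#' @param between_module_corr log-scale correlation between regions in
#'   different modules.
#' @param region_mean_volumes 64 positive means (mm^3), raw scale.
#' @param region_sd 64 positive standard deviations (mm^3), raw scale.
#'   Log-normal parameters are moment-matched so that raw-scale means and
#'   SDs are exactly these values.
#' @param workflow_bias named list of per-region multiplicative bias vectors,
#'   one per workflow; see [default_workflow_bias()].
#' @param workflow_noise_sd named numeric, log-scale SD of subject-specific
#'   multiplicative stripping error per workflow (default 0 for all: biases
#'   are then the only difference between workflows).  Non-zero values
#'   emulate run-to-run variability of automatic skull stripping, which is
#'   what makes workflows differ in network topology (a purely deterministic
#'   rescaling leaves correlations unchanged).  Noise factors are
#'   mean-corrected so the expected bias stays at `workflow_bias`.
#' @param repeat_sd within-subject measurement SD (mm^3) used by
#'   [generate_repeats()].
#' @param atlas region atlas.
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_subjects = 22L, seed = 1L, n_modules = 4L,
                          within_module_corr = 0.6,
                          between_module_corr = 0.1,
                          region_mean_volumes = default_region_means(atlas),
                          region_sd = 0.12 * region_mean_volumes,
                          workflow_bias = default_workflow_bias(atlas),
                          workflow_noise_sd = NULL,
                          repeat_sd = 50,
                          atlas = load_region_atlas()) {
  stopifnot(n_subjects >= 1, n_modules >= 1,
            within_module_corr > 0, within_module_corr < 1,
            between_module_corr >= 0, between_module_corr < 1,
            length(region_mean_volumes) == 64L,
            all(region_mean_volumes > 0),
            length(region_sd) == 64L, all(region_sd > 0))
  if (repeat_sd < 0) stop("'repeat_sd' must be >= 0", call. = FALSE)
  if (!is.list(workflow_bias) || is.null(names(workflow_bias))) {
    stop("'workflow_bias' must be a named list of bias vectors", call. = FALSE)
  }
  for (w in names(workflow_bias)) {
    b <- workflow_bias[[w]]
    if (length(b) != 64L || any(!is.finite(b)) || any(b <= 0)) {
      stop("bias vector for workflow '", w,
           "' must be 64 strictly positive values", call. = FALSE)
    }
  }
  if (is.null(workflow_noise_sd)) {
    workflow_noise_sd <- stats::setNames(rep(0, length(workflow_bias)),
                                         names(workflow_bias))
  }
  if (any(workflow_noise_sd < 0)) {
    stop("'workflow_noise_sd' must be >= 0", call. = FALSE)
  }
  missing_sd <- setdiff(names(workflow_bias), names(workflow_noise_sd))
  if (length(missing_sd) > 0L) {
    workflow_noise_sd[missing_sd] <- 0
  }
  R <- block_correlation(n_modules, within_module_corr, between_module_corr)
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) {
    stop("implied 64x64 correlation matrix is not positive definite; ",
         "lower 'within_module_corr' or raise 'between_module_corr'",
         call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
         n_modules = as.integer(n_modules),
         within_module_corr = within_module_corr,
         between_module_corr = between_module_corr,
         region_mean_volumes = region_mean_volumes,
         region_sd = region_sd,
         workflow_bias = workflow_bias,
         workflow_noise_sd = workflow_noise_sd,
         repeat_sd = repeat_sd, atlas = atlas, chol_corr = ch),
    class = "cohort_config")
}

#' Exchangeable block correlation matrix over the 64 atlas regions
#'
#' Regions are split into `n_modules` contiguous blocks of (near-)equal size
#' in atlas order; correlation is `within` inside a block and `between`
#' across blocks.
#'
#' @param n_modules number of modules.
#' @param within within-module correlation.
#' @param between between-module correlation.
#' @param p number of regions (default 64).
#' @return a `p` x `p` correlation matrix.
#' @export
block_correlation <- function(n_modules, within, between, p = 64L) {
  module <- module_assignment(n_modules, p)
  R <- matrix(between, p, p)
  for (m in seq_len(n_modules)) {
    idx <- which(module == m)
    R[idx, idx] <- within
  }
  diag(R) <- 1
  R
}

#' @rdname block_correlation
#' @return `module_assignment()`: integer vector mapping each region to its
#'   module.
#' @export
module_assignment <- function(n_modules, p = 64L) {
  sort(rep_len(seq_len(n_modules), p))
}

# Latent (bias-free) raw-scale volumes for one cohort: log-normal with
# moment-matched raw means/SDs and block-correlated Gaussian log-scores.
.draw_latent <- function(config) {
  n <- config$n_subjects
  mu <- config$region_mean_volumes
  cv2 <- (config$region_sd / mu)^2
  sigma_log <- sqrt(log(1 + cv2))
  mu_log <- log(mu) - sigma_log^2 / 2
  Z <- matrix(stats::rnorm(n * 64L), n, 64L) %*% config$chol_corr
  V <- exp(sweep(sweep(Z, 2L, sigma_log, "*"), 2L, mu_log, "+"))
  colnames(V) <- region_labels(config$atlas)
  rownames(V) <- sprintf("subject%02d", seq_len(n))
  V
}

#' Generate a synthetic cohort for each skull-stripping workflow
#'
#' Draws one set of latent subject volumes and derives one volume table per
#' workflow by applying that workflow's multiplicative bias (and, if
#' configured, subject-specific log-normal stripping noise).  The latent
#' draw is shared, so biases (and noise) are the only differences between
#' workflows.
#'
#' @param config a [cohort_config()].
#' @return named list of [volume_table()] objects, one per workflow.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  latent <- .draw_latent(config)
  out <- list()
  for (w in names(config$workflow_bias)) {
    vals <- sweep(latent, 2L, config$workflow_bias[[w]], "*")
    sd_w <- config$workflow_noise_sd[[w]]
    if (sd_w > 0) {
      eps <- matrix(stats::rnorm(length(vals), 0, sd_w), nrow(vals))
      vals <- vals * exp(eps - sd_w^2 / 2)  # mean-corrected noise factor
    }
    out[[w]] <- volume_table(vals, workflow = w, atlas = config$atlas)
  }
  out
}

#' Generate repeated measurements sharing latent subject volumes
#'
#' Emulates a test-retest design on the unbiased (manually corrected)
#' workflow: all repeats share one latent draw of true subject volumes, and
#' each measurement adds independent zero-mean Gaussian noise with SD
#' `config$repeat_sd` on the raw (mm^3) scale.
#'
#' @param config a [cohort_config()].
#' @param n_repeats number of repeated measurements (>= 2).
#' @return list of [volume_table()] objects with `measurement_id` 1..n.
#' @export
generate_repeats <- function(config, n_repeats = 2L) {
  stopifnot(inherits(config, "cohort_config"))
  if (n_repeats < 2L) stop("'n_repeats' must be >= 2", call. = FALSE)
  set.seed(config$seed)
  latent <- .draw_latent(config)
  out <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    noise <- matrix(stats::rnorm(length(latent), 0, config$repeat_sd),
                    nrow(latent))
    vals <- latent + noise
    if (any(vals <= 0)) {
      stop("measurement noise produced non-positive volumes; ",
           "reduce 'repeat_sd' relative to the region means", call. = FALSE)
    }
    out[[r]] <- volume_table(vals, workflow = "iBEAT_corrected",
                             measurement_id = r, atlas = config$atlas)
  }
  out
}
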