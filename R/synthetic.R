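#' Parameters for the synthetic three-cohort FPKM generator
#'
#' Defaults emulate the statistical structure of the duodenal study the
#' pipeline targets: 20,120 mapped transcripts; cohorts of 30 (stunting),
#' 27 (SAM) and 37 (adult) samples; a log-normal expression backbone shared
#' by all cohorts; ~2.5% of genes planted per direction in the stunting
#' contrast and 4% per direction in the SAM contrast (half of the stunting
#' effects shared with SAM, same direction, reflecting overlapping
#' enteropathy signatures); HIV-positive fractions of 0/33%/32% that carry
#' no expression effect by default.
#'
#' @param n_genes Number of transcripts (default 20120; minimum 100).
#' @param cohort_sizes Named integer vector (stunting, SAM, adult); each >= 2.
#' @param baseline_log2_mean,baseline_log2_sd Log2 mean/sd of the per-gene
#'   baseline expression (defaults 3.0, 2.5).
#' @param zero_gene_fraction Fraction of genes forced to a near-zero
#'   baseline, log2 level -6 (default 0.10).
#' @param per_gene_noise_sd_range Range (length 2) of per-gene log2 noise sd,
#'   drawn uniformly (default c(0.25, 0.60)).
#' @param planted_fraction_stunting,planted_fraction_sam Fraction of genes
#'   planted per direction in each child cohort vs the adult baseline
#'   (defaults 0.025 and 0.04).
#' @param effect_log2_mean,effect_log2_sd Mean/sd of the absolute planted
#'   log2 effect (defaults 1.8, 0.5).
#' @param shared_enteropathy_fraction Fraction of stunting-planted genes also
#'   planted in SAM with the same sign (default 0.5).
#' @param hiv_positive_fraction Named vector of HIV-positive fractions per
#'   cohort (defaults stunting 0, SAM 0.33, adult 0.32).
#' @param hiv_effect_log2 Optional log2 expression shift applied to
#'   HIV-positive samples of planted HIV genes; 0 disables (default 0).
#' @param seed Integer seed driving all randomness.
#' @return A validated parameter list of class "synth_params".
#' @export
synth_params <- function(n_genes = 20120L,
                         cohort_sizes = c(stunting = 30L, SAM = 27L, adult = 37L),
                         baseline_log2_mean = 3.0,
                         baseline_log2_sd = 2.5,
                         zero_gene_fraction = 0.10,
                         per_gene_noise_sd_range = c(0.25, 0.60),
                         planted_fraction_stunting = 0.025,
                         planted_fraction_sam = 0.04,
                         effect_log2_mean = 1.8,
                         effect_log2_sd = 0.5,
                         shared_enteropathy_fraction = 0.5,
                         hiv_positive_fraction = c(stunting = 0, SAM = 0.33, adult = 0.32),
                         hiv_effect_log2 = 0,
                         seed = 42L) {
  p <- list(n_genes = as.integer(n_genes), cohort_sizes = cohort_sizes,
            baseline_log2_mean = baseline_log2_mean,
            baseline_log2_sd = baseline_log2_sd,
            zero_gene_fraction = zero_gene_fraction,
            per_gene_noise_sd_range = per_gene_noise_sd_range,
            planted_fraction_stunting = planted_fraction_stunting,
            planted_fraction_sam = planted_fraction_sam,
            effect_log2_mean = effect_log2_mean,
            effect_log2_sd = effect_log2_sd,
            shared_enteropathy_fraction = shared_enteropathy_fraction,
            hiv_positive_fraction = hiv_positive_fraction,
            hiv_effect_log2 = hiv_effect_log2,
            seed = as.integer(seed))
  class(p) <- "synth_params"
  validate_synth_params(p)
  p
}

validate_synth_params <- function(p) {
  if (p$n_genes < 100L) stop("n_genes must be at least 100")
  req <- cohort_levels()
  if (!all(req %in% names(p$cohort_sizes)))
    stop("cohort_sizes must name ", paste(req, collapse = ", "))
  if (any(p$cohort_sizes < 2L)) stop("every cohort needs at least 2 samples")
  fracs <- c(p$zero_gene_fraction, p$planted_fraction_stunting,
             p$planted_fraction_sam, p$shared_enteropathy_fraction,
             p$hiv_positive_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (length(p$per_gene_noise_sd_range) != 2L ||
      any(p$per_gene_noise_sd_range < 0) ||
      diff(p$per_gene_noise_sd_range) < 0)
    stop("per_gene_noise_sd_range must be a non-decreasing pair of non-negative sds")
  if (p$baseline_log2_sd < 0 || p$effect_log2_sd < 0) stop("sds must be non-negative")
  invisible(p)
}

#' Generate a synthetic three-cohort FPKM dataset with planted truth
#'
#' Log-normal generative model: each gene g has a baseline log2 level
#' b_g ~ Normal(baseline_log2_mean, baseline_log2_sd) (zero genes are forced
#' to b_g = -6), cohort effects delta (log2, vs the adult baseline) planted
#' in the child cohorts, and per-sample noise e ~ Normal(0, sigma_g) with
#' sigma_g ~ Uniform(per_gene_noise_sd_range). The FPKM value of gene g in
#' sample s of cohort c is 2^(b_g + delta_gc + e_gs); values below 1e-4 are
#' floored to 0. Effects are planted only on non-zero genes. Fully
#' reproducible from the seed.
#'
#' @param params A "synth_params" list from [synth_params()].
#' @return A list:
#'   \describe{
#'     \item{matrix}{gene x sample FPKM matrix (genes g00001...);}
#'     \item{design}{design data.frame (sample_id, cohort, hiv);}
#'     \item{truth}{data.frame `gene_id`, `delta_stunting`, `delta_sam`
#'       (log2 effects vs the adult baseline; 0 when not planted),
#'       `is_zero_gene`.}
#'   }
#' @export
generate_dataset <- function(params = synth_params()) {
  validate_synth_params(params)
  set.seed(params$seed)
  ng <- params$n_genes
  sizes <- params$cohort_sizes[cohort_levels()]
  gene_ids <- sprintf("g%05d", seq_len(ng))

  baseline <- stats::rnorm(ng, params$baseline_log2_mean, params$baseline_log2_sd)
  n_zero <- round(params$zero_gene_fraction * ng)
  zero_idx <- if (n_zero > 0) sample.int(ng, n_zero) else integer(0)
  baseline[zero_idx] <- -6
  is_zero <- seq_len(ng) %in% zero_idx
  sigma <- stats::runif(ng, params$per_gene_noise_sd_range[1],
                        params$per_gene_noise_sd_range[2])

  nonzero <- which(!is_zero)
  draw_effect <- function(n, sign) sign * abs(stats::rnorm(n, params$effect_log2_mean,
                                                           params$effect_log2_sd))
  delta_stunting <- numeric(ng)
  delta_sam <- numeric(ng)

  n_st <- round(params$planted_fraction_stunting * ng)   # per direction
  st_planted <- sample(nonzero, min(2L * n_st, length(nonzero)))
  st_up <- st_planted[seq_len(n_st)]
  st_dn <- st_planted[seq_len(n_st) + n_st]
  delta_stunting[st_up] <- draw_effect(length(st_up), +1)
  delta_stunting[st_dn] <- draw_effect(length(st_dn), -1)

  # shared enteropathy signal: a fraction of stunting effects recur in SAM
  n_shared <- round(params$shared_enteropathy_fraction * length(st_planted))
  shared <- if (n_shared > 0) sample(st_planted, n_shared) else integer(0)
  delta_sam[shared] <- sign(delta_stunting[shared]) *
    abs(stats::rnorm(length(shared), params$effect_log2_mean, params$effect_log2_sd))

  # SAM-only planting tops each direction up to the SAM planted fraction
  n_sam <- round(params$planted_fraction_sam * ng)       # per direction
  free <- setdiff(nonzero, st_planted)
  need_up <- max(0L, n_sam - sum(delta_sam > 0))
  need_dn <- max(0L, n_sam - sum(delta_sam < 0))
  sam_extra <- sample(free, min(need_up + need_dn, length(free)))
  sam_up <- sam_extra[seq_len(need_up)]
  sam_dn <- sam_extra[need_up + seq_len(need_dn)]
  delta_sam[sam_up] <- draw_effect(length(sam_up), +1)
  delta_sam[sam_dn] <- draw_effect(length(sam_dn), -1)

  deltas <- cbind(stunting = delta_stunting, SAM = delta_sam, adult = 0)
  sample_ids <- unlist(lapply(cohort_levels(), function(co) {
    sprintf("%s_%02d", co, seq_len(sizes[[co]]))
  }), use.names = FALSE)
  cohort_of <- rep(cohort_levels(), times = sizes)

  values <- matrix(0, nrow = ng, ncol = length(sample_ids),
                   dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    mu <- baseline + deltas[, cohort_of[j]]
    values[, j] <- 2^(mu + stats::rnorm(ng, 0, sigma))
  }
  values[values < 1e-4] <- 0

  hiv <- unlist(lapply(cohort_levels(), function(co) {
    n <- sizes[[co]]
    n_pos <- round(params$hiv_positive_fraction[[co]] * n)
    status <- rep("neg", n)
    if (n_pos > 0) status[sample.int(n, n_pos)] <- "pos"
    status
  }), use.names = FALSE)

  if (params$hiv_effect_log2 != 0) {
    # optional knob: shift HIV-positive samples on 1% of non-zero genes
    hiv_genes <- sample(nonzero, max(1L, round(0.01 * ng)))
    pos_cols <- which(hiv == "pos")
    values[hiv_genes, pos_cols] <- values[hiv_genes, pos_cols] * 2^params$hiv_effect_log2
  }

  design <- data.frame(sample_id = sample_ids,
                       cohort = factor(cohort_of, levels = cohort_levels()),
                       hiv = hiv, stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = gene_ids,
                      delta_stunting = delta_stunting,
                      delta_sam = delta_sam,
                      is_zero_gene = is_zero,
                      stringsAsFactors = FALSE)
  list(matrix = values, design = design, truth = truth)
}

#' Query planted genes above an effect-size threshold
#'
#' @param truth Truth data.frame from [generate_dataset()].
#' @param contrast "stunting" or "SAM" (effect vs the adult baseline).
#' @param min_abs_log2 Non-negative threshold on |log2 effect| (boundary
#'   inclusive).
#' @return A list with `up` and `down` character vectors of gene ids.
#' @export
truth_table <- function(truth, contrast = c("stunting", "SAM"),
                        min_abs_log2 = 0) {
  contrast <- match.arg(contrast)
  if (min_abs_log2 < 0) stop("min_abs_log2 must be non-negative")
  delta <- if (contrast == "stunting") truth$delta_stunting else truth$delta_sam
  planted <- delta != 0 & abs(delta) >= min_abs_log2
  list(up = truth$gene_id[planted & delta > 0],
       down = truth$gene_id[planted & delta < 0])
}
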