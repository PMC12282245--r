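# Synthetic electropherogram simulator: peak tables and raw traces with
# truth labels for any diploid genotype expressible in a panel.

#' Simulation parameters
#'
#' Peak heights are multiplicative: `base_height * efficiency * copies *
#' lognormal noise`. The two dosage pairs (alpha1/alpha2 share an upstream
#' primer; Y1/Y2 share both primers) receive a shared pair-level noise
#' component controlled by `pair_correlation`, so at the default
#' `noise_cv = 0.07` the SD of a simulated dosage ratio matches the
#' published per-class ratio spread (~0.07 around ratio 1) rather than the
#' sqrt(2)-inflated value fully independent peak noise would give.
#'
#' @param base_height Per-copy amplicon height (RFU).
#' @param efficiency Named per-target multiplicative amplification factors
#'   (unnamed targets default to 1). The `"table1"` preset of
#'   [efficiency_preset()] reproduces the published measured ratio means.
#' @param noise_cv Coefficient of variation of lognormal height noise.
#' @param pair_correlation Correlation of log-heights within a dosage pair
#'   (0 = independent, in `[0, 1)`).
#' @param scale_sd SD of a shared lognormal per-sample amplification factor
#'   (classification must be invariant to it).
#' @param size_jitter_sd SD of fragment-size measurement error (bp).
#' @param dropout_height Peaks below this height (RFU) are omitted.
#' @param sigma_peak Gaussian peak width on traces (scans).
#' @param scan_offset,scans_per_bp Affine fragment-migration map:
#'   `scan = scan_offset + scans_per_bp * size`.
#' @param scan_count Trace length (scans).
#' @param baseline Constant trace baseline (RFU).
#' @param ladder_height Ladder fragment height (RFU).
#' @return A `thal_sim_params` list.
#' @export
sim_params <- function(base_height = 2000, efficiency = numeric(),
                       noise_cv = 0.07, pair_correlation = 0.5,
                       scale_sd = 0, size_jitter_sd = 0.15,
                       dropout_height = 50, sigma_peak = 3,
                       scan_offset = 200, scans_per_bp = 12,
                       scan_count = 7800, baseline = 10,
                       ladder_height = 1200) {
  stopifnot(base_height > 0, noise_cv >= 0,
            pair_correlation >= 0, pair_correlation < 1)
  structure(list(base_height = base_height, efficiency = efficiency,
                 noise_cv = noise_cv, pair_correlation = pair_correlation,
                 scale_sd = scale_sd, size_jitter_sd = size_jitter_sd,
                 dropout_height = dropout_height, sigma_peak = sigma_peak,
                 scan_offset = scan_offset, scans_per_bp = scans_per_bp,
                 scan_count = scan_count, baseline = baseline,
                 ladder_height = ladder_height),
            class = "thal_sim_params")
}

#' Per-target efficiency presets
#'
#' `"unit"` sets every target to 1. `"table1"` skews the dosage amplicons so
#' that cohort-mean measured ratios reproduce the published per-class means
#' (e.g. alpha1/alpha2 near 1.04 for the wild type instead of exactly 1),
#' emulating the systematic primer-efficiency deviations seen on real
#' samples.
#'
#' @param name `"unit"` or `"table1"`.
#' @return Named numeric vector usable as `efficiency` in [sim_params()].
#' @export
efficiency_preset <- function(name = c("unit", "table1")) {
  name <- match.arg(name)
  if (name == "unit") return(numeric())
  # Wild-type measured means: a1/a2 = 1.04, Y1/Y2 = 0.92.
  c(alpha1 = 1.04, alpha2 = 1.00, Y1 = 0.92, Y2 = 1.00)
}

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

.sim_pair_of <- function(target) {
  if (target %in% c("alpha1", "alpha2")) "alpha_pair"
  else if (target %in% c("Y1", "Y2")) "y_pair"
  else NA_character_
}

#' Simulate one sample's peak table
#'
#' Every target in the genotype's expected peak set is rendered as one peak:
#' height proportional to its amplicon dose with multiplicative lognormal
#' noise, size jittered around the target's expected size. Peaks falling
#' below `dropout_height` are omitted. Deterministic given `seed`.
#'
#' @param genotype List with `alpha` and `beta` allele-name pairs.
#' @param panel A `thal_panel`.
#' @param params A [sim_params()] object.
#' @param seed Integer seed (`NULL` = use current RNG state).
#' @param sample_id Sample identifier.
#' @return A `thal_sim_sample`: list with `truth`, `peak_table`.
#' @export
simulate_peak_table <- function(genotype, panel, params = sim_params(),
                                seed = NULL, sample_id = "sim") {
  stopifnot(inherits(panel, "thal_panel"))
  counts <- expected_peak_counts(genotype, panel)
  .with_seed(seed, {
    present <- names(counts)[counts > 0L]
    tg <- panel$targets[match(present, panel$targets$name), , drop = FALSE]
    n <- nrow(tg)
    eff <- rep(1, n)
    has_eff <- match(tg$name, names(params$efficiency))
    eff[!is.na(has_eff)] <- params$efficiency[has_eff[!is.na(has_eff)]]

    sdlog <- params$noise_cv  # cv ~ sdlog for small cv
    rho <- params$pair_correlation
    sd_shared <- sdlog * sqrt(rho)
    sd_ind <- sdlog * sqrt(1 - rho)
    pair_z <- c(alpha_pair = stats::rnorm(1), y_pair = stats::rnorm(1))
    pair_of <- vapply(tg$name, .sim_pair_of, character(1))
    log_noise <- ifelse(!is.na(pair_of),
                        sd_shared * pair_z[pair_of] +
                          sd_ind * stats::rnorm(n),
                        sdlog * stats::rnorm(n))
    scale <- if (params$scale_sd > 0)
      exp(stats::rnorm(1, 0, params$scale_sd)) else 1
    height <- params$base_height * eff * counts[present] * scale *
      exp(log_noise)
    size <- tg$expected_size +
      if (params$size_jitter_sd > 0)
        stats::rnorm(n, 0, params$size_jitter_sd) else 0
    keep <- height >= params$dropout_height
    peaks <- data.frame(dye = tg$dye[keep], size = size[keep],
                        height = unname(height[keep]),
                        area = rep(NA_real_, sum(keep)),
                        scan_position = rep(NA_integer_, sum(keep)),
                        stringsAsFactors = FALSE)
    structure(list(truth = genotype,
                   peak_table = peak_table(sample_id, peaks)),
              class = "thal_sim_sample")
  })
}

#' Render a simulated sample as a raw trace
#'
#' Each peak becomes a Gaussian (apex = peak height) at the scan position
#' given by the affine size-to-scan map; the LIZ channel carries the full
#' ladder; a constant baseline is added to every channel.
#'
#' @param sample A `thal_sim_sample` (or bare `thal_peak_table`).
#' @param panel A `thal_panel` (for the ladder sizes).
#' @param params A [sim_params()] object.
#' @return A `thal_trace`.
#' @export
simulate_trace <- function(sample, panel, params = sim_params()) {
  tab <- if (inherits(sample, "thal_sim_sample")) sample$peak_table
  else sample
  stopifnot(inherits(tab, "thal_peak_table"))
  to_scan <- function(bp) params$scan_offset + params$scans_per_bp * bp
  max_bp <- (params$scan_count - params$scan_offset) / params$scans_per_bp
  if (any(tab$peaks$size > max_bp, na.rm = TRUE))
    stop("peak size beyond the scan map range", call. = FALSE)
  scans <- seq_len(params$scan_count)
  ch <- list()
  for (dye in c("FAM", "VIC", "NED")) {
    y <- rep(params$baseline, params$scan_count)
    rows <- which(tab$peaks$dye == dye)
    for (i in rows) {
      mu <- to_scan(tab$peaks$size[i])
      y <- y + tab$peaks$height[i] *
        exp(-((scans - mu)^2) / (2 * params$sigma_peak^2))
    }
    ch[[dye]] <- y
  }
  y <- rep(params$baseline, params$scan_count)
  for (bp in panel$ladder_sizes) {
    mu <- to_scan(bp)
    y <- y + params$ladder_height *
      exp(-((scans - mu)^2) / (2 * params$sigma_peak^2))
  }
  ch$LIZ <- y
  sample_trace(tab$sample_id, ch)
}

#' Simulate a cohort with a truth manifest
#'
#' @param genotype_spec List of `list(genotype = ..., n = ...)` entries.
#' @param panel A `thal_panel`.
#' @param params A [sim_params()] object.
#' @param seed Master seed; per-sample seeds are derived from it.
#' @param id_prefix Sample-id prefix.
#' @return List with `samples` (list of `thal_sim_sample`) and `manifest`
#'   (`data.frame`: `sample_id, alpha1, alpha2, beta1, beta2`).
#' @export
simulate_cohort <- function(genotype_spec, panel, params = sim_params(),
                            seed = 1L, id_prefix = "S") {
  ns <- vapply(genotype_spec, function(g) as.integer(g$n), integer(1))
  if (any(ns <= 0L)) stop("each cohort entry needs n > 0", call. = FALSE)
  total <- sum(ns)
  seeds <- .with_seed(seed, sample.int(.Machine$integer.max - 1L, total))
  samples <- vector("list", total)
  man <- vector("list", total)
  k <- 0L
  for (entry in genotype_spec) {
    for (r in seq_len(entry$n)) {
      k <- k + 1L
      sid <- sprintf("%s%04d", id_prefix, k)
      samples[[k]] <- simulate_peak_table(entry$genotype, panel, params,
                                          seed = seeds[k], sample_id = sid)
      man[[k]] <- data.frame(sample_id = sid,
                             alpha1 = entry$genotype$alpha[1],
                             alpha2 = entry$genotype$alpha[2],
                             beta1 = entry$genotype$beta[1],
                             beta2 = entry$genotype$beta[2],
                             stringsAsFactors = FALSE)
    }
  }
  list(samples = samples, manifest = do.call(rbind, man))
}
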