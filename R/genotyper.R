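# Genotype calling: dosage-ratio copy-number classification, channel
# mutation/wild-type interpretation, control QC, and rule-based assembly of
# every diploid genotype consistent with the evidence.

#' Calling thresholds
#'
#' @param min_height Peak-detection apex threshold on traces (RFU).
#' @param min_prominence Peak-detection prominence threshold (RFU).
#' @param window Baseline rolling-minimum window (scans).
#' @param min_ladder_points Minimum matched size-standard points.
#' @param residual_tolerance Ladder leave-one-out residual tolerance (bp).
#' @param max_z Maximum combined standardized log-ratio distance for a
#'   copy-number call.
#' @param tie_margin Minimum score separation between the two best
#'   copy-number classes; closer calls are refused.
#' @return A `thal_calling_params` list.
#' @export
calling_params <- function(min_height = 50, min_prominence = 25,
                           window = 51L, min_ladder_points = 8L,
                           residual_tolerance = 1.0, max_z = 4.0,
                           tie_margin = 0.5) {
  structure(list(min_height = min_height, min_prominence = min_prominence,
                 window = window, min_ladder_points = min_ladder_points,
                 residual_tolerance = residual_tolerance, max_z = max_z,
                 tie_margin = tie_margin), class = "thal_calling_params")
}

#' Internal-control QC
#'
#' GAPDH (FAM) and AMEL (VIC) must amplify above the analytical threshold in
#' every sample; a missing control makes the sample uninterpretable.
#'
#' @param binding A `thal_binding`.
#' @param panel A `thal_panel`.
#' @return Character vector of QC flags (empty = pass).
#' @export
check_controls <- function(binding, panel) {
  flags <- character()
  for (ctrl in c("GAPDH", "AMEL")) {
    h <- bound_height(binding, ctrl)
    if (h < panel$analytical_min_height)
      flags <- c(flags, paste0("CONTROL_", ctrl, "_MISSING"))
  }
  flags
}

#' Dosage peak heights and ratios
#'
#' @param binding A `thal_binding`.
#' @return A `thal_ratio_measurement`: heights of alpha1/alpha2/Y1/Y2 (0
#'   when absent), `a_ratio` and `y_ratio` (`NA` when the denominator peak
#'   is absent), and the `absent` subset.
#' @export
compute_ratios <- function(binding) {
  h <- vapply(CNV_TARGETS, function(t) bound_height(binding, t), numeric(1))
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(heights = h,
                 a_ratio = ratio(h[["alpha1"]], h[["alpha2"]]),
                 y_ratio = ratio(h[["Y1"]], h[["Y2"]]),
                 absent = CNV_TARGETS[h == 0]),
            class = "thal_ratio_measurement")
}

#' Classify the alpha-cluster copy-number configuration
#'
#' Candidate classes are first filtered to those whose zero-copy pattern
#' matches the observed absences. Survivors are ranked by penalized
#' Gaussian negative log-likelihood in log-ratio space,
#' `sum(z^2)/2 + sum(log sd) - log(prior)`, over the defined ratio
#' dimensions with per-class delta-method log SDs and class prior weights
#' (extended, unvalidated configurations are strongly down-weighted). The
#' best class is called unless its combined standardized distance
#' `sqrt(z_a^2 + z_y^2)` exceeds `max_z` or the runner-up's penalized
#' likelihood is within `tie_margin` (log units).
#'
#' @param m A `thal_ratio_measurement`.
#' @param panel A `thal_panel`.
#' @param max_z,tie_margin See [calling_params()].
#' @return A `thal_cnv_call`: `class_key`, `label`, `score`, `no_call_reason`
#'   (`NA` when called), `candidates` (scored class table),
#'   `total_absence`.
#' @export
classify_cnv <- function(m, panel, max_z = 4.0, tie_margin = 0.5) {
  cls <- panel$ratio_classes
  pattern <- paste(sort(m$absent, method = "radix"), collapse = ",")
  cls_pattern <- vapply(strsplit(cls$absent, ","), function(x)
    paste(sort(x, method = "radix"), collapse = ","), character(1))
  surv <- cls[cls_pattern == pattern, , drop = FALSE]
  out <- function(key, label, score, reason, cand) {
    structure(list(class_key = key, label = label, score = score,
                   no_call_reason = reason, candidates = cand,
                   total_absence = length(m$absent) == 4L),
              class = "thal_cnv_call")
  }
  if (nrow(surv) == 0L)
    return(out(NA_character_, "NO_CALL", NA_real_,
               "ABSENCE_PATTERN_UNMATCHED", surv))
  score <- nll <- numeric(nrow(surv))
  for (i in seq_len(nrow(surv))) {
    z2 <- 0
    logsd <- 0
    if (surv$a_num[i] > 0 && surv$a_den[i] > 0) {
      z2 <- z2 + ((log(m$a_ratio) - log(surv$a_num[i] / surv$a_den[i])) /
                    surv$sd_log_a[i])^2
      logsd <- logsd + log(surv$sd_log_a[i])
    }
    if (surv$y_num[i] > 0 && surv$y_den[i] > 0) {
      z2 <- z2 + ((log(m$y_ratio) - log(surv$y_num[i] / surv$y_den[i])) /
                    surv$sd_log_y[i])^2
      logsd <- logsd + log(surv$sd_log_y[i])
    }
    score[i] <- sqrt(z2)
    nll[i] <- z2 / 2 + logsd - log(surv$class_prior[i])
  }
  surv$score <- score
  surv$penalized_nll <- nll
  surv <- surv[order(surv$penalized_nll), , drop = FALSE]
  if (surv$score[1] > max_z)
    return(out(NA_character_, "NO_CALL", surv$score[1],
               "SCORE_EXCEEDS_MAX_Z", surv))
  if (nrow(surv) >= 2L &&
      (surv$penalized_nll[2] - surv$penalized_nll[1]) < tie_margin)
    return(out(NA_character_, "NO_CALL", surv$score[1], "AMBIGUOUS_TIE",
               surv))
  out(surv$key[1], surv$label[1], surv$score[1], NA_character_, surv)
}

#' Interpret mutation and wild-type-control peaks
#'
#' A mutation peak with its paired wild-type control present is a
#' heterozygote; with the control absent, a homozygote; sites with no
#' wild-type control in the panel cannot be resolved (`HET_OR_HOM`).
#'
#' @param binding A `thal_binding`.
#' @param panel A `thal_panel`.
#' @return `data.frame`: `target`, `site` (allele name), `cluster`,
#'   `zygosity` in `HET`/`HOM`/`HET_OR_HOM` for each detected mutation.
#' @export
call_mutations <- function(binding, panel) {
  tg <- panel$targets
  muts <- tg[tg$role == "point_mutation", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(muts))) {
    if (is.null(binding$assignments[[muts$name[i]]])) next
    site <- muts$variant_link[i]
    wt_name <- paste0("wt_", site)
    has_wt <- wt_name %in% tg$name
    zyg <- if (!has_wt) "HET_OR_HOM"
    else if (!is.null(binding$assignments[[wt_name]])) "HET" else "HOM"
    rows[[length(rows) + 1L]] <- data.frame(
      target = muts$name[i], site = site,
      cluster = .get_allele(panel, site)$cluster, zygosity = zyg,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(target = character(), site = character(),
                      cluster = character(), zygosity = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Collect the evidence set from bound peaks
#'
#' @param binding A `thal_binding`.
#' @param panel A `thal_panel`.
#' @param cnv A `thal_cnv_call` (computed from the same binding when
#'   omitted).
#' @param max_z,tie_margin Passed to [classify_cnv()] in that case.
#' @return A `thal_evidence`: the CNV call, detected mutation table,
#'   breakpoint markers, wild-type control presence/absence, ratios, and
#'   control QC flags.
#' @export
evidence_set <- function(binding, panel, cnv = NULL, max_z = 4.0,
                         tie_margin = 0.5) {
  m <- compute_ratios(binding)
  if (is.null(cnv)) cnv <- classify_cnv(m, panel, max_z, tie_margin)
  tg <- panel$targets
  present <- bound_targets(binding)
  wt_all <- tg$name[tg$role == "wildtype_control"]
  structure(list(
    cnv = cnv, ratios = m,
    mutations = call_mutations(binding, panel),
    markers_present = intersect(tg$name[tg$role == "deletion_breakpoint"],
                                present),
    wt_present = intersect(wt_all, present),
    wt_absent = setdiff(wt_all, present),
    qc = check_controls(binding, panel)), class = "thal_evidence")
}

.format_pair <- function(pair) paste(pair, collapse = "/")

#' Format a diploid genotype label
#' @param genotype List with `alpha`, `beta` pairs.
#' @return Single string, e.g. `"aWSa/--SEA; bCD37/bN"`.
#' @export
format_genotype <- function(genotype)
  paste(.format_pair(genotype$alpha), .format_pair(genotype$beta),
        sep = "; ")

.sig_obs_alpha <- function(evidence, panel) {
  wt_sites <- attr(panel$alpha_pairs, "wt_sites")
  alpha_targets <- panel$targets$name[
    panel$targets$role %in% c("deletion_breakpoint", "point_mutation") &
      panel$targets$variant_link %in% names(panel$alleles)[vapply(
        panel$alleles, function(a) a$cluster == "alpha", logical(1))]]
  markers <- sort(intersect(evidence$markers_present, alpha_targets),
                  method = "radix")
  muts <- sort(intersect(evidence$mutations$target, alpha_targets),
               method = "radix")
  wt_bits <- as.integer(paste0("wt_", wt_sites) %in% evidence$wt_present)
  paste(evidence$cnv$class_key, paste(markers, collapse = ";"),
        paste(muts, collapse = ";"), paste(wt_bits, collapse = ""),
        sep = "|")
}

.sig_obs_beta <- function(evidence, panel) {
  wt_sites <- attr(panel$beta_pairs, "wt_sites")
  beta_alleles <- names(panel$alleles)[vapply(panel$alleles, function(a)
    a$cluster == "beta", logical(1))]
  beta_targets <- panel$targets$name[
    panel$targets$role %in% c("deletion_breakpoint", "point_mutation") &
      panel$targets$variant_link %in% beta_alleles]
  markers <- sort(intersect(evidence$markers_present, beta_targets),
                  method = "radix")
  muts <- sort(intersect(evidence$mutations$target, beta_targets),
               method = "radix")
  wt_bits <- as.integer(paste0("wt_", wt_sites) %in% evidence$wt_present)
  paste(paste(markers, collapse = ";"), paste(muts, collapse = ";"),
        paste(wt_bits, collapse = ""), sep = "|")
}

#' Assemble all diploid genotypes consistent with the evidence
#'
#' Enumerates unordered alpha-allele pairs and beta-allele pairs from the
#' panel catalog and keeps those whose predicted evidence (copy-number
#' class, breakpoint markers, mutation peaks, wild-type-control
#' presence/absence) exactly matches the observation. One consistent
#' genotype is an `OK` call; several are `AMBIGUOUS` (all listed, fewest
#' variant alleles first); none is a `NO_CALL` with the failed side
#' recorded. Control failure short-circuits to `UNINTERPRETABLE`.
#'
#' @param evidence A `thal_evidence`.
#' @param panel A `thal_panel`.
#' @return A `thal_genotype_call`.
#' @export
assemble_genotype <- function(evidence, panel) {
  mk <- function(status, genotypes, qc, explanation)
    structure(list(status = status, genotypes = genotypes, qc_flags = qc,
                   evidence = evidence, explanation = explanation),
              class = "thal_genotype_call")
  qc <- evidence$qc
  if (length(qc))
    return(mk("UNINTERPRETABLE", list(), qc,
              "internal control below the analytical threshold"))
  if (!is.na(evidence$cnv$no_call_reason))
    return(mk("NO_CALL", list(), paste0("CNV_", evidence$cnv$no_call_reason),
              "copy-number class could not be called"))

  a_hit <- panel$alpha_pairs[
    panel$alpha_pairs$sig == .sig_obs_alpha(evidence, panel), , drop = FALSE]
  b_hit <- panel$beta_pairs[
    panel$beta_pairs$sig == .sig_obs_beta(evidence, panel), , drop = FALSE]
  if (nrow(a_hit) == 0L || nrow(b_hit) == 0L) {
    side <- c(if (nrow(a_hit) == 0L) "alpha", if (nrow(b_hit) == 0L) "beta")
    return(mk("NO_CALL", list(), "EVIDENCE_CONFLICT",
              paste0("no ", paste(side, collapse = " or "),
                     " allele pair reproduces the observed evidence")))
  }
  combos <- expand.grid(a = seq_len(nrow(a_hit)), b = seq_len(nrow(b_hit)))
  nvar <- a_hit$n_variant[combos$a] + b_hit$n_variant[combos$b]
  combos <- combos[order(nvar), , drop = FALSE]
  genotypes <- lapply(seq_len(nrow(combos)), function(k)
    list(alpha = c(a_hit$a1[combos$a[k]], a_hit$a2[combos$a[k]]),
         beta = c(b_hit$b1[combos$b[k]], b_hit$b2[combos$b[k]])))

  flags <- character()
  ambiguous <- length(genotypes) > 1L
  if (ambiguous && nrow(evidence$mutations) &&
      any(evidence$mutations$zygosity == "HET_OR_HOM"))
    flags <- c(flags, "ZYGOSITY_UNRESOLVED")
  beta_del_markers <- panel$targets$name[
    panel$targets$role == "deletion_breakpoint" &
      panel$targets$variant_link %in% names(panel$alleles)[vapply(
        panel$alleles, function(a) a$cluster == "beta", logical(1))]]
  if (ambiguous && length(intersect(evidence$markers_present,
                                    beta_del_markers)) &&
      !("ZYGOSITY_UNRESOLVED" %in% flags))
    flags <- c(flags, "ZYGOSITY_UNRESOLVED")
  if (nrow(a_hit) > 1L)
    flags <- c(flags, "CNV_COMPENSATED_ALTERNATES")
  if (evidence$cnv$total_absence) flags <- c(flags, "TOTAL_ABSENCE")
  low <- any(vapply(genotypes, function(g)
    any(vapply(c(g$alpha, g$beta), function(n)
      panel$alleles[[n]]$low_confidence, logical(1))), logical(1)))
  if (low) flags <- c(flags, "LOW_CONFIDENCE_ALLELE")

  status <- if (length(genotypes) == 1L) "OK" else "AMBIGUOUS"
  expl <- sprintf(
    "class %s; markers [%s]; mutations [%s]; %d consistent genotype(s)",
    evidence$cnv$label,
    paste(evidence$markers_present, collapse = ", "),
    paste(evidence$mutations$target, collapse = ", "), length(genotypes))
  mk(status, genotypes, flags, expl)
}

#' @export
print.thal_genotype_call <- function(x, ...) {
  cat("<thal_genotype_call>", x$status, "\n")
  for (g in x$genotypes) cat("  ", format_genotype(g), "\n")
  if (length(x$qc_flags)) cat("  flags:", paste(x$qc_flags, collapse = ", "),
                              "\n")
  invisible(x)
}

#' Call one sample end-to-end
#'
#' Accepts either a peak table or a raw trace. Traces are peak-detected,
#' size-calibrated against the LIZ ladder (calibration failure makes the
#' sample uninterpretable) and sized. Peaks below the panel's analytical
#' threshold are discarded before binding; bound evidence then flows
#' through control QC, ratio classification, mutation interpretation and
#' genotype assembly.
#'
#' @param x A `thal_peak_table`, `thal_sim_sample`, or `thal_trace`.
#' @param panel A `thal_panel`.
#' @param params A [calling_params()] object.
#' @return A `thal_genotype_call` with `sample_id`, `ratios` and `cnv`
#'   attached.
#' @export
call_sample <- function(x, panel, params = calling_params()) {
  if (inherits(x, "thal_sim_sample")) x <- x$peak_table
  if (inherits(x, "thal_trace")) {
    pk <- detect_peaks(x, min_height = params$min_height,
                       min_prominence = params$min_prominence,
                       window = params$window)
    cal <- fit_size_ladder(pk, panel$ladder_sizes,
                           min_ladder_points = params$min_ladder_points,
                           residual_tolerance = params$residual_tolerance)
    if (inherits(cal, "thal_ladder_failure")) {
      call <- structure(list(status = "UNINTERPRETABLE", genotypes = list(),
                             qc_flags = "LADDER_FAILURE", evidence = NULL,
                             explanation = cal$reason),
                        class = "thal_genotype_call")
      call$sample_id <- x$sample_id
      return(call)
    }
    peaks <- assign_sizes(pk[pk$dye != "LIZ", , drop = FALSE], cal)
    sid <- x$sample_id
  } else {
    stopifnot(inherits(x, "thal_peak_table"))
    peaks <- x$peaks
    sid <- x$sample_id
  }
  peaks <- peaks[peaks$height >= panel$analytical_min_height, , drop = FALSE]
  binding <- bind_peaks(peaks, panel)
  ev <- evidence_set(binding, panel, max_z = params$max_z,
                     tie_margin = params$tie_margin)
  call <- assemble_genotype(ev, panel)
  call$sample_id <- sid
  call$ratios <- ev$ratios
  call$cnv <- ev$cnv
  call$binding <- binding
  call
}

#' One-row summary record of a call
#'
#' @param call A `thal_genotype_call`.
#' @return One-row `data.frame`: `sample_id, status, genotypes, a_ratio,
#'   y_ratio, cnv_class, qc_flags`.
#' @export
call_record <- function(call) {
  data.frame(
    sample_id = call$sample_id %||% NA_character_,
    status = call$status,
    genotypes = paste(vapply(call$genotypes, format_genotype, character(1)),
                      collapse = " | "),
    a_ratio = if (is.null(call$ratios)) NA_real_ else call$ratios$a_ratio,
    y_ratio = if (is.null(call$ratios)) NA_real_ else call$ratios$y_ratio,
    cnv_class = if (is.null(call$cnv)) NA_character_ else call$cnv$label,
    qc_flags = paste(call$qc_flags, collapse = ","),
    stringsAsFactors = FALSE)
}

#' Call a list of samples
#'
#' @param samples List of peak tables / simulated samples / traces.
#' @param panel A `thal_panel`.
#' @param params A [calling_params()] object.
#' @return List with `calls` and a cohort `records` data.frame.
#' @export
call_cohort <- function(samples, panel, params = calling_params()) {
  calls <- lapply(samples, call_sample, panel = panel, params = params)
  list(calls = calls, records = do.call(rbind, lapply(calls, call_record)))
}

.is_wildtype_truth <- function(truth)
  all(truth$alpha == "aa") && all(truth$beta == "bN")

.same_genotype <- function(g, truth) {
  setequal_pair <- function(x, y)
    identical(sort(x), sort(y))
  setequal_pair(g$alpha, truth$alpha) && setequal_pair(g$beta, truth$beta)
}

#' Truth-containment of a call
#' @param call A `thal_genotype_call`.
#' @param truth Genotype list (`alpha`, `beta`).
#' @return `TRUE` when the truth genotype is among the called genotypes.
#' @export
call_contains_truth <- function(call, truth)
  any(vapply(call$genotypes, .same_genotype, logical(1), truth = truth))

#' Concordance of calls against a truth manifest
#'
#' Negatives are samples whose truth is fully wild-type; positives carry at
#' least one variant allele. A sample is concordant when its truth genotype
#' is in the call set.
#'
#' @param calls List of `thal_genotype_call`.
#' @param manifest `data.frame` with `sample_id, alpha1, alpha2, beta1,
#'   beta2`.
#' @return List of counts and rates (`negative_concordance`,
#'   `positive_concordance`, `overall_accuracy`, `n_uninterpretable`).
#' @export
concordance_summary <- function(calls, manifest) {
  ids <- vapply(calls, function(c) c$sample_id %||% NA_character_,
                character(1))
  m <- match(manifest$sample_id, ids)
  stopifnot(!any(is.na(m)))
  neg_ok <- neg_n <- pos_ok <- pos_n <- unint <- 0L
  for (i in seq_len(nrow(manifest))) {
    truth <- list(alpha = c(manifest$alpha1[i], manifest$alpha2[i]),
                  beta = c(manifest$beta1[i], manifest$beta2[i]))
    call <- calls[[m[i]]]
    ok <- call$status %in% c("OK", "AMBIGUOUS") &&
      call_contains_truth(call, truth)
    if (call$status == "UNINTERPRETABLE") unint <- unint + 1L
    if (.is_wildtype_truth(truth)) {
      neg_n <- neg_n + 1L; if (ok) neg_ok <- neg_ok + 1L
    } else {
      pos_n <- pos_n + 1L; if (ok) pos_ok <- pos_ok + 1L
    }
  }
  list(n = neg_n + pos_n, n_negative = neg_n, n_positive = pos_n,
       n_uninterpretable = unint,
       negative_concordance = if (neg_n) neg_ok / neg_n else NA_real_,
       positive_concordance = if (pos_n) pos_ok / pos_n else NA_real_,
       overall_accuracy = (neg_ok + pos_ok) / (neg_n + pos_n))
}
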