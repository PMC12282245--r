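# Panel model: targets, alleles, copy-number classes, and the predictions
# the genotyper checks observed evidence against.

#' @keywords internal
DYE_LEVELS <- c("FAM", "VIC", "NED", "LIZ")

#' @keywords internal
CNV_TARGETS <- c("alpha1", "alpha2", "Y1", "Y2")

TARGET_ROLES <- c("cnv_reference", "deletion_breakpoint", "point_mutation",
                  "wildtype_control", "internal_control")

#' Construct an amplicon target row
#'
#' @param name Unique target identifier.
#' @param dye Dye channel, one of FAM/VIC/NED (LIZ is reserved for the ladder).
#' @param expected_size Expected amplicon size in bp.
#' @param role One of `cnv_reference`, `deletion_breakpoint`,
#'   `point_mutation`, `wildtype_control`, `internal_control`.
#' @param variant_link Allele name this target evidences (`NA` for
#'   `cnv_reference` / `internal_control`).
#' @return One-row `data.frame`.
#' @export
amplicon_target <- function(name, dye, expected_size, role,
                            variant_link = NA_character_) {
  data.frame(name = as.character(name), dye = as.character(dye),
             expected_size = as.numeric(expected_size),
             role = as.character(role),
             variant_link = as.character(variant_link),
             stringsAsFactors = FALSE)
}

#' Construct an allele definition
#'
#' An allele is one chromosome-level configuration: for the alpha cluster it
#' carries a copy count (0, 1 or 2) for each of the four dosage amplicons
#' alpha1, alpha2, Y1 and Y2; deletion alleles additionally amplify
#' breakpoint (gap) markers, and non-deletion alleles carry one
#' allele-specific mutation amplicon.
#'
#' @param name Allele identifier (e.g. `"aa"`, `"-a3.7"`, `"bCD17"`).
#' @param cluster `"alpha"` or `"beta"`.
#' @param copies Named integer vector over `alpha1, alpha2, Y1, Y2`
#'   (alpha alleles only; `NULL` for beta).
#' @param markers Character vector of deletion-breakpoint target names this
#'   allele amplifies.
#' @param point_mutation `TRUE` if the allele carries its own
#'   allele-specific mutation amplicon (`mut_<name>`).
#' @param deletes_sites Point-variant sites (allele names) whose wild-type
#'   control amplicon cannot amplify from this allele because the region is
#'   deleted (whole-cluster deletions).
#' @param low_confidence Flag for alleles whose dosage behaviour is a
#'   modelling default rather than a validated value.
#' @param rank Display rank used to order genotype pairs (normal allele
#'   last, severe deletions late).
#' @return A list of class `thal_allele`.
#' @export
allele_def <- function(name, cluster, copies = NULL, markers = character(),
                       point_mutation = FALSE, deletes_sites = character(),
                       low_confidence = FALSE, rank = 50L) {
  cluster <- match.arg(cluster, c("alpha", "beta"))
  if (cluster == "alpha") {
    if (is.null(copies) || !all(CNV_TARGETS %in% names(copies)))
      stop("alpha allele '", name, "' needs a complete copy map over ",
           paste(CNV_TARGETS, collapse = ", "), call. = FALSE)
    copies <- as.integer(copies[CNV_TARGETS])
    names(copies) <- CNV_TARGETS
    if (any(is.na(copies)) || any(copies < 0L) || any(copies > 2L))
      stop("copy counts for '", name, "' must be integers in {0, 1, 2}",
           call. = FALSE)
  } else {
    copies <- NULL
  }
  structure(list(name = as.character(name), cluster = cluster,
                 copies = copies, markers = as.character(markers),
                 point_mutation = isTRUE(point_mutation),
                 deletes_sites = as.character(deletes_sites),
                 low_confidence = isTRUE(low_confidence),
                 rank = as.integer(rank)),
            class = "thal_allele")
}

# ---------------------------------------------------------------------------
# Default panel catalog

.alpha_allele_table <- function() {
  # Copy maps are the unique small-integer solution reproducing the published
  # theoretical alpha1:alpha2 and Y1:Y2 ratios of each heterozygote-with-
  # normal class under summation of the two alleles.
  list(
    allele_def("aCSa",   "alpha", c(alpha1 = 1, alpha2 = 1, Y1 = 1, Y2 = 1),
               point_mutation = TRUE, rank = 1L),
    allele_def("aQSa",   "alpha", c(alpha1 = 1, alpha2 = 1, Y1 = 1, Y2 = 1),
               point_mutation = TRUE, rank = 2L),
    allele_def("aWSa",   "alpha", c(alpha1 = 1, alpha2 = 1, Y1 = 1, Y2 = 1),
               point_mutation = TRUE, rank = 3L),
    allele_def("aCD30a", "alpha", c(alpha1 = 1, alpha2 = 1, Y1 = 1, Y2 = 1),
               point_mutation = TRUE, rank = 4L),
    allele_def("aCD74a", "alpha", c(alpha1 = 1, alpha2 = 1, Y1 = 1, Y2 = 1),
               point_mutation = TRUE, rank = 5L),
    allele_def("-a3.7",  "alpha", c(alpha1 = 1, alpha2 = 0, Y1 = 0, Y2 = 1),
               rank = 6L),
    allele_def("-a4.2",  "alpha", c(alpha1 = 1, alpha2 = 0, Y1 = 1, Y2 = 0),
               rank = 7L),
    allele_def("-a2.4",  "alpha", c(alpha1 = 1, alpha2 = 0, Y1 = 1, Y2 = 0),
               markers = "gap_a2.4", low_confidence = TRUE, rank = 8L),
    allele_def("-a21.9", "alpha", c(alpha1 = 1, alpha2 = 0, Y1 = 1, Y2 = 0),
               markers = "gap_a21.9", low_confidence = TRUE, rank = 9L),
    allele_def("-a27.6", "alpha", c(alpha1 = 1, alpha2 = 0, Y1 = 1, Y2 = 0),
               markers = "gap_a27.6", low_confidence = TRUE, rank = 10L),
    allele_def("fusion", "alpha", c(alpha1 = 1, alpha2 = 0, Y1 = 1, Y2 = 0),
               markers = "gap_fusion", low_confidence = TRUE, rank = 11L),
    allele_def("aaa_anti3.7", "alpha",
               c(alpha1 = 1, alpha2 = 2, Y1 = 2, Y2 = 1), rank = 12L),
    allele_def("aaa_anti4.2", "alpha",
               c(alpha1 = 1, alpha2 = 2, Y1 = 1, Y2 = 2), rank = 13L),
    allele_def("HKaa",   "alpha", c(alpha1 = 1, alpha2 = 1, Y1 = 0, Y2 = 2),
               rank = 14L),
    allele_def("--SEA",  "alpha", c(alpha1 = 0, alpha2 = 0, Y1 = 0, Y2 = 0),
               markers = "gap_SEA",
               deletes_sites = c("aCSa", "aQSa", "aWSa", "aCD30a", "aCD74a"),
               rank = 15L),
    allele_def("--THAI", "alpha", c(alpha1 = 0, alpha2 = 0, Y1 = 0, Y2 = 0),
               markers = "gap_THAI",
               deletes_sites = c("aCSa", "aQSa", "aWSa", "aCD30a", "aCD74a"),
               rank = 16L),
    allele_def("aa",     "alpha", c(alpha1 = 1, alpha2 = 1, Y1 = 1, Y2 = 1),
               rank = 99L)
  )
}

.beta_point_names <- function() {
  c("b-90", "b-50", "b-29", "b-28", "bCap+40-43", "bInitCD", "bCD5",
    "bCD14/15", "bCD17", "bCD26", "bCD27/28", "bIVS-I-1", "bIVS-I-5",
    "bCD37", "bCD41/42", "bCD43", "bCD54-58", "bCD71/72", "bCD95",
    "bIVS-II-5", "bIVS-II-654")
}

# Beta point variants carrying a NED wild-type control amplicon in the
# default panel; bCD37 deliberately has none, so its heterozygote and
# homozygote are indistinguishable (reported as an ambiguity).
.beta_wt_controlled <- function() {
  c("bCD17", "bCD41/42", "bIVS-II-654", "b-28", "bCD26", "bCD71/72",
    "bCD27/28", "bCD43", "bIVS-I-1")
}

.alpha_wt_controlled <- function() c("aCSa", "aQSa", "aWSa")

.beta_allele_table <- function() {
  pts <- .beta_point_names()
  out <- vector("list", length(pts) + 4L)
  for (i in seq_along(pts))
    out[[i]] <- allele_def(pts[i], "beta", point_mutation = TRUE,
                           rank = as.integer(i))
  n <- length(pts)
  out[[n + 1L]] <- allele_def("bDEL-Chinese", "beta",
                              markers = "gap_Chinese", rank = n + 1L)
  out[[n + 2L]] <- allele_def("bDEL-SEA-HPFH", "beta",
                              markers = "gap_SEA-HPFH", rank = n + 2L)
  out[[n + 3L]] <- allele_def("bDEL-Taiwanese", "beta",
                              markers = "gap_Taiwanese", rank = n + 3L)
  out[[n + 4L]] <- allele_def("bN", "beta", rank = 99L)
  out
}

# Sizes of the published GeneScan-600-LIZ-style ladder series (bp).
#' Default size-standard fragment sizes (bp)
#' @return Numeric vector of ladder fragment sizes.
#' @export
default_ladder_sizes <- function() {
  c(20, 40, 60, 80, 100, 114, 120, 140, 160, 180, 200, 214, 220, 240,
    250, 260, 280, 300, 314, 320, 340, 360, 380, 400, 414, 420, 440,
    460, 480, 500, 514, 520, 540, 560, 580, 600)
}

.default_targets <- function(alleles) {
  # Exact amplicon sizes are panel metadata, not published; a deterministic
  # grid (start 85 bp, step 4 bp per dye) satisfies the >= 3 bp same-dye
  # spacing and the 80-600 bp range.
  rows <- list()
  add <- function(name, dye, role, link = NA_character_)
    rows[[length(rows) + 1L]] <<- list(name = name, dye = dye, role = role,
                                       variant_link = link)
  # FAM: housekeeping control + all beta-side variant amplicons
  add("GAPDH", "FAM", "internal_control")
  for (b in .beta_point_names()) add(paste0("mut_", b), "FAM",
                                     "point_mutation", b)
  add("gap_Chinese",   "FAM", "deletion_breakpoint", "bDEL-Chinese")
  add("gap_SEA-HPFH",  "FAM", "deletion_breakpoint", "bDEL-SEA-HPFH")
  add("gap_Taiwanese", "FAM", "deletion_breakpoint", "bDEL-Taiwanese")
  # VIC: AMEL control, Y1/Y2 dosage pair, alpha-side variant amplicons
  add("AMEL", "VIC", "internal_control")
  add("Y1", "VIC", "cnv_reference")
  add("Y2", "VIC", "cnv_reference")
  for (a in c("aCSa", "aQSa", "aWSa", "aCD30a", "aCD74a"))
    add(paste0("mut_", a), "VIC", "point_mutation", a)
  for (g in c("gap_SEA", "gap_THAI", "gap_a2.4", "gap_a21.9", "gap_a27.6",
              "gap_fusion"))
    add(g, "VIC", "deletion_breakpoint",
        c(gap_SEA = "--SEA", gap_THAI = "--THAI", gap_a2.4 = "-a2.4",
          gap_a21.9 = "-a21.9", gap_a27.6 = "-a27.6",
          gap_fusion = "fusion")[[g]])
  # NED: alpha1/alpha2 dosage pair + wild-type control amplicons
  add("alpha1", "NED", "cnv_reference")
  add("alpha2", "NED", "cnv_reference")
  for (s in c(.alpha_wt_controlled(), .beta_wt_controlled()))
    add(paste0("wt_", s), "NED", "wildtype_control", s)

  df <- do.call(rbind, lapply(rows, function(r)
    amplicon_target(r$name, r$dye, NA_real_, r$role, r$variant_link)))
  for (dye in c("FAM", "VIC", "NED")) {
    idx <- which(df$dye == dye)
    df$expected_size[idx] <- 85 + 4 * (seq_along(idx) - 1L)
  }
  rownames(df) <- NULL
  df
}

# ---------------------------------------------------------------------------
# Ratio arithmetic (exact, integer)

.gcd <- function(a, b) if (b == 0L) a else .gcd(b, a %% b)

# Reduced "n:d" part for one dosage ratio; zeros are kept explicit so the
# string doubles as the absence pattern.
.ratio_part <- function(num, den) {
  num <- as.integer(num); den <- as.integer(den)
  if (num == 0L && den == 0L) return("0:0")
  if (num == 0L) return("0:1")
  if (den == 0L) return("1:0")
  g <- .gcd(num, den)
  paste0(num %/% g, ":", den %/% g)
}

.ratio_key <- function(sums) {
  paste(.ratio_part(sums[["alpha1"]], sums[["alpha2"]]),
        .ratio_part(sums[["Y1"]], sums[["Y2"]]), sep = "|")
}

.absent_pattern <- function(sums) CNV_TARGETS[sums == 0L]

# ---------------------------------------------------------------------------

.get_allele <- function(panel, name) {
  a <- panel$alleles[[name]]
  if (is.null(a)) stop("unknown allele '", name, "'", call. = FALSE)
  a
}

#' Summed alpha-cluster copy numbers for an allele pair
#'
#' Adds the per-allele copy counts of the four dosage amplicons for the two
#' alpha alleles of a diploid genotype.
#'
#' @param alpha_pair Character vector of two alpha allele names.
#' @param panel A `thal_panel`.
#' @return Named integer vector over `alpha1, alpha2, Y1, Y2`.
#' @export
#' @examples
#' p <- default_panel()
#' expected_copy_numbers(c("-a3.7", "aa"), p)
expected_copy_numbers <- function(alpha_pair, panel) {
  stopifnot(length(alpha_pair) == 2L)
  a1 <- .get_allele(panel, alpha_pair[[1]])
  a2 <- .get_allele(panel, alpha_pair[[2]])
  if (a1$cluster != "alpha" || a2$cluster != "alpha")
    stop("expected_copy_numbers() takes two alpha alleles", call. = FALSE)
  if (is.null(a1$copies) || is.null(a2$copies))
    stop("allele missing copy map", call. = FALSE)
  a1$copies + a2$copies
}

#' Theoretical alpha1/alpha2 and Y1/Y2 ratios for an alpha allele pair
#'
#' Ratios are exact rationals over summed copy counts. A ratio whose
#' denominator copy sum is zero is undefined; when all four sums are zero
#' (double whole-cluster deletion, the hydrops configuration) the result
#' carries a `total_absence` flag.
#'
#' @inheritParams expected_copy_numbers
#' @return List with `a` and `y` (each `c(num, den)` reduced, or `NULL` when
#'   undefined), `a_value`/`y_value` numeric ratios (`NA` when undefined),
#'   `absent` (dosage targets with copy sum 0) and `total_absence`.
#' @export
#' @examples
#' expected_ratio(c("HKaa", "aa"), default_panel())
expected_ratio <- function(alpha_pair, panel) {
  sums <- expected_copy_numbers(alpha_pair, panel)
  red <- function(num, den) {
    if (den == 0L) return(NULL)
    if (num == 0L) return(c(0L, 1L))
    g <- .gcd(num, den)
    c(num %/% g, den %/% g)
  }
  a <- red(sums[["alpha1"]], sums[["alpha2"]])
  y <- red(sums[["Y1"]], sums[["Y2"]])
  list(a = a, y = y,
       a_value = if (is.null(a)) NA_real_ else a[1] / a[2],
       y_value = if (is.null(y)) NA_real_ else y[1] / y[2],
       absent = .absent_pattern(sums),
       total_absence = all(sums == 0L))
}

#' Targets with positive expected signal for a diploid genotype
#'
#' @param genotype List with `alpha` and `beta`, each a character vector of
#'   two allele names.
#' @param panel A `thal_panel`.
#' @return Character vector of target names.
#' @export
expected_peak_set <- function(genotype, panel) {
  counts <- expected_peak_counts(genotype, panel)
  names(counts)[counts > 0L]
}

#' Expected per-target amplicon dose for a diploid genotype
#'
#' Copy counts drive simulated peak heights: dosage amplicons contribute the
#' summed cluster copies, variant and control amplicons one unit per
#' carrying allele, internal controls two (one per chromosome).
#'
#' @inheritParams expected_peak_set
#' @return Named integer vector over all panel targets (0 = no signal).
#' @export
expected_peak_counts <- function(genotype, panel) {
  alleles <- lapply(c(genotype$alpha, genotype$beta),
                    function(n) .get_allele(panel, n))
  targets <- panel$targets
  counts <- stats::setNames(integer(nrow(targets)), targets$name)

  sums <- expected_copy_numbers(genotype$alpha, panel)
  counts[CNV_TARGETS] <- sums[CNV_TARGETS]
  counts[targets$name[targets$role == "internal_control"]] <- 2L

  for (al in alleles) {
    for (m in al$markers) counts[[m]] <- counts[[m]] + 1L
    if (al$point_mutation) {
      t <- paste0("mut_", al$name)
      counts[[t]] <- counts[[t]] + 1L
    }
  }
  wt <- targets[targets$role == "wildtype_control", , drop = FALSE]
  for (i in seq_len(nrow(wt))) {
    site <- wt$variant_link[i]
    site_cluster <- .get_allele(panel, site)$cluster
    n_wt <- sum(vapply(alleles, function(al)
      al$cluster == site_cluster && al$name != site &&
        !(site %in% al$deletes_sites), logical(1)))
    counts[[wt$name[i]]] <- as.integer(n_wt)
  }
  counts
}

#' Variant allele catalog of a panel
#'
#' @param panel A `thal_panel`.
#' @return List with `alpha` and `beta` character vectors of variant
#'   (non-normal) allele names.
#' @export
genotype_catalog <- function(panel) {
  nm <- names(panel$alleles)
  cl <- vapply(panel$alleles, function(a) a$cluster, character(1))
  list(alpha = setdiff(nm[cl == "alpha"], "aa"),
       beta = setdiff(nm[cl == "beta"], "bN"))
}

# ---------------------------------------------------------------------------
# Ratio classes

# Published per-class measured ratios (mean +/- SD) for the six validated
# heterozygote-with-normal copy-number classes.
.validated_ratio_classes <- function() {
  data.frame(
    key = c("1:1|1:1", "2:1|1:2", "2:1|2:1", "2:3|3:2", "2:3|2:3",
            "1:1|1:3"),
    label = c("aa/aa", "-a3.7/aa", "-a4.2/aa", "aaa_anti3.7/aa",
              "aaa_anti4.2/aa", "HKaa/aa"),
    measured_mean_a = c(1.04, 2.02, 1.88, 0.74, 0.57, 0.97),
    measured_sd_a   = c(0.07, 0.14, 0.15, 0.11, 0.10, 0.10),
    measured_mean_y = c(0.92, 0.48, 2.05, 1.52, 0.53, 0.35),
    measured_sd_y   = c(0.07, 0.04, 0.18, 0.09, 0.03, 0.03),
    stringsAsFactors = FALSE)
}

.build_ratio_classes <- function(alleles) {
  anames <- names(alleles)[vapply(alleles, function(a)
    a$cluster == "alpha", logical(1))]
  seen <- new.env(parent = emptyenv())
  rows <- list()
  for (i in seq_along(anames)) for (j in i:length(anames)) {
    s <- alleles[[anames[i]]]$copies + alleles[[anames[j]]]$copies
    key <- .ratio_key(s)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      key = key,
      a_num = s[["alpha1"]], a_den = s[["alpha2"]],
      y_num = s[["Y1"]], y_den = s[["Y2"]],
      absent = paste(.absent_pattern(s), collapse = ","),
      stringsAsFactors = FALSE)
  }
  cls <- do.call(rbind, rows)
  val <- .validated_ratio_classes()
  m <- match(cls$key, val$key)
  cls$validated <- !is.na(m)
  cls$label <- ifelse(cls$validated, val$label[m], cls$key)
  for (col in c("measured_mean_a", "measured_sd_a",
                "measured_mean_y", "measured_sd_y"))
    cls[[col]] <- val[[col]][m]
  # delta-method log-scale SDs; extended (unvalidated) classes inherit the
  # largest validated spread
  sdl <- function(sd, mean) sd / mean
  max_sdl <- max(sdl(val$measured_sd_a, val$measured_mean_a),
                 sdl(val$measured_sd_y, val$measured_mean_y))
  cls$sd_log_a <- ifelse(cls$validated,
                         sdl(val$measured_sd_a, val$measured_mean_a)[m],
                         max_sdl)
  cls$sd_log_y <- ifelse(cls$validated,
                         sdl(val$measured_sd_y, val$measured_mean_y)[m],
                         max_sdl)
  # class prior weights: extended configurations (homozygous triplications,
  # trans compounds) are orders of magnitude rarer in screening populations
  # than the validated carrier classes
  cls$class_prior <- ifelse(cls$validated, 1, 1e-3)
  rownames(cls) <- NULL
  cls
}

# ---------------------------------------------------------------------------
# Pair signature tables (precomputed predicted evidence per unordered
# allele pair; makes genotype assembly a vector lookup)

.alpha_pair_table <- function(panel) {
  cat <- names(panel$alleles)
  anames <- cat[vapply(panel$alleles, function(a) a$cluster == "alpha",
                       logical(1))]
  wt_sites <- panel$targets$variant_link[
    panel$targets$role == "wildtype_control"]
  wt_sites <- wt_sites[vapply(wt_sites, function(s)
    .get_allele(panel, s)$cluster == "alpha", logical(1))]
  rows <- list()
  for (i in seq_along(anames)) for (j in i:length(anames)) {
    pair <- c(anames[i], anames[j])
    als <- lapply(pair, function(n) panel$alleles[[n]])
    key <- .ratio_key(als[[1]]$copies + als[[2]]$copies)
    markers <- sort(unique(as.character(unlist(lapply(als, `[[`,
                                                      "markers")))),
                    method = "radix")
    carriers <- unique(pair[vapply(als, `[[`, logical(1),
                                   "point_mutation")])
    muts <- if (length(carriers)) sort(paste0("mut_", carriers),
                                       method = "radix")
    else character()
    wt_bits <- vapply(wt_sites, function(s)
      any(vapply(als, function(al)
        al$name != s && !(s %in% al$deletes_sites), logical(1))),
      logical(1))
    nvar <- sum(pair != "aa")
    rows[[length(rows) + 1L]] <- data.frame(
      a1 = pair[1], a2 = pair[2],
      sig = paste(key, paste(markers, collapse = ";"),
                  paste(muts, collapse = ";"),
                  paste(as.integer(wt_bits), collapse = ""), sep = "|"),
      class_key = key, n_variant = nvar, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  attr(tab, "wt_sites") <- unname(unlist(wt_sites))
  tab
}

.beta_pair_table <- function(panel) {
  bnames <- names(panel$alleles)[vapply(panel$alleles, function(a)
    a$cluster == "beta", logical(1))]
  wt_sites <- panel$targets$variant_link[
    panel$targets$role == "wildtype_control"]
  wt_sites <- wt_sites[vapply(wt_sites, function(s)
    .get_allele(panel, s)$cluster == "beta", logical(1))]
  rows <- list()
  for (i in seq_along(bnames)) for (j in i:length(bnames)) {
    pair <- c(bnames[i], bnames[j])
    als <- lapply(pair, function(n) panel$alleles[[n]])
    markers <- sort(unique(as.character(unlist(lapply(als, `[[`,
                                                      "markers")))),
                    method = "radix")
    carriers <- unique(pair[vapply(als, `[[`, logical(1),
                                   "point_mutation")])
    muts <- if (length(carriers)) sort(paste0("mut_", carriers),
                                       method = "radix")
    else character()
    wt_bits <- vapply(wt_sites, function(s)
      any(vapply(als, function(al)
        al$name != s && !(s %in% al$deletes_sites), logical(1))),
      logical(1))
    rows[[length(rows) + 1L]] <- data.frame(
      b1 = pair[1], b2 = pair[2],
      sig = paste(paste(markers, collapse = ";"),
                  paste(muts, collapse = ";"),
                  paste(as.integer(wt_bits), collapse = ""), sep = "|"),
      n_variant = sum(pair != "bN"), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  attr(tab, "wt_sites") <- unname(unlist(wt_sites))
  tab
}

# ---------------------------------------------------------------------------
# Panel constructor / validation / IO

#' Construct a panel definition
#'
#' Builds the derived tables (ratio classes, per-pair evidence signatures)
#' from the target and allele catalogs. Structural problems (missing copy
#' maps, unknown dyes) raise an error of class `thal_panel_structure_error`;
#' design-rule violations are left for [validate_panel()].
#'
#' @param targets `data.frame` of amplicon targets (see [amplicon_target()]).
#' @param alleles List of [allele_def()] objects.
#' @param min_same_dye_spacing Minimum spacing (bp) between same-dye
#'   amplicons; the assay guarantees at least 3 bp.
#' @param size_tolerance Peak-to-target binding tolerance (bp).
#' @param analytical_min_height Analytical peak-height threshold (RFU);
#'   peaks below it are not interpreted.
#' @param ladder_sizes Size-standard fragment sizes (bp).
#' @param version Free-form panel version string.
#' @return A `thal_panel` object.
#' @export
new_panel <- function(targets, alleles, min_same_dye_spacing = 3,
                      size_tolerance = 1.4, analytical_min_height = 200,
                      ladder_sizes = default_ladder_sizes(),
                      version = "unversioned") {
  serr <- function(...) stop(structure(class = c("thal_panel_structure_error",
                                                 "error", "condition"),
                                       list(message = paste0(...),
                                            call = NULL)))
  need <- c("name", "dye", "expected_size", "role", "variant_link")
  if (!is.data.frame(targets) || !all(need %in% names(targets)))
    serr("targets must be a data.frame with columns ",
         paste(need, collapse = ", "))
  if (!all(targets$dye %in% DYE_LEVELS))
    serr("unknown dye(s): ",
         paste(setdiff(targets$dye, DYE_LEVELS), collapse = ", "))
  if (!all(targets$role %in% TARGET_ROLES))
    serr("unknown role(s): ",
         paste(setdiff(targets$role, TARGET_ROLES), collapse = ", "))
  if (!all(vapply(alleles, inherits, logical(1), "thal_allele")))
    serr("alleles must be a list of allele_def() objects")
  names(alleles) <- vapply(alleles, `[[`, character(1), "name")
  if (anyDuplicated(names(alleles)))
    serr("duplicate allele names")

  panel <- structure(list(
    targets = targets, alleles = alleles,
    min_same_dye_spacing = min_same_dye_spacing,
    size_tolerance = size_tolerance,
    analytical_min_height = analytical_min_height,
    ladder_sizes = sort(as.numeric(ladder_sizes)),
    version = version), class = "thal_panel")
  panel$ratio_classes <- .build_ratio_classes(alleles)
  panel$alpha_pairs <- .alpha_pair_table(panel)
  panel$beta_pairs <- .beta_pair_table(panel)
  panel
}

#' The default shipped thalassemia panel
#'
#' Covers 16 alpha and 24 beta variant alleles: the five homologous-
#' recombination configurations called from dosage ratios, whole-cluster and
#' rare alpha deletions and beta deletions called from breakpoint amplicons,
#' and non-deletion point variants called from allele-specific amplicons
#' with NED wild-type controls for a configurable subset of sites.
#'
#' @param ... Overrides passed to [new_panel()] thresholds.
#' @return A `thal_panel`.
#' @export
default_panel <- function(...) {
  alleles <- c(.alpha_allele_table(), .beta_allele_table())
  new_panel(.default_targets(alleles), alleles, version = "default-1", ...)
}

#' Validate a panel against the assay design rules
#'
#' Checks amplicon sizes (80-600 bp), same-dye spacing, name uniqueness,
#' wild-type-control linkage, presence of the GAPDH (FAM) and AMEL (VIC)
#' internal controls, completeness of alpha copy maps, and that the LIZ
#' channel carries no panel targets.
#'
#' @param panel A `thal_panel`.
#' @return `data.frame` with columns `rule`, `detail`, `message`; zero rows
#'   when the panel is valid.
#' @export
validate_panel <- function(panel) {
  v <- list()
  bad <- function(rule, detail, message)
    v[[length(v) + 1L]] <<- data.frame(rule = rule, detail = detail,
                                       message = message,
                                       stringsAsFactors = FALSE)
  tg <- panel$targets
  out <- tg$expected_size < 80 | tg$expected_size > 600
  for (i in which(out))
    bad("size_range", tg$name[i],
        sprintf("size out of 80-600 range (%.1f bp)", tg$expected_size[i]))
  for (dye in setdiff(unique(tg$dye), "LIZ")) {
    sz <- sort(tg$expected_size[tg$dye == dye])
    gaps <- diff(sz)
    for (k in which(gaps < panel$min_same_dye_spacing))
      bad("same_dye_spacing", dye,
          sprintf("same-dye spacing < %g bp in %s (%.1f vs %.1f bp)",
                  panel$min_same_dye_spacing, dye, sz[k], sz[k + 1]))
  }
  if (anyDuplicated(tg$name))
    for (n in unique(tg$name[duplicated(tg$name)]))
      bad("unique_names", n, sprintf("duplicate target name '%s'", n))
  wt <- tg[tg$role == "wildtype_control", , drop = FALSE]
  mut_links <- tg$variant_link[tg$role == "point_mutation"]
  for (i in seq_len(nrow(wt)))
    if (!(wt$variant_link[i] %in% mut_links))
      bad("wt_control_link", wt$name[i],
          sprintf("wildtype_control '%s' has no matching point_mutation target",
                  wt$name[i]))
  if (!any(tg$name == "GAPDH" & tg$dye == "FAM" &
             tg$role == "internal_control"))
    bad("internal_controls", "GAPDH", "missing GAPDH internal control (FAM)")
  if (!any(tg$name == "AMEL" & tg$dye == "VIC" &
             tg$role == "internal_control"))
    bad("internal_controls", "AMEL", "missing AMEL internal control (VIC)")
  for (al in panel$alleles)
    if (al$cluster == "alpha" &&
        (is.null(al$copies) || !all(CNV_TARGETS %in% names(al$copies))))
      bad("alpha_copy_map", al$name,
          sprintf("alpha allele '%s' lacks a complete copy map", al$name))
  for (i in which(tg$dye == "LIZ"))
    bad("liz_reserved", tg$name[i],
        sprintf("target '%s' assigned to the LIZ ladder channel", tg$name[i]))
  if (length(v) == 0L)
    return(data.frame(rule = character(), detail = character(),
                      message = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}

#' Write a panel definition to YAML
#'
#' @param panel A `thal_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  al <- lapply(panel$alleles, function(a) {
    x <- list(cluster = a$cluster)
    if (!is.null(a$copies)) x$copies <- as.list(a$copies)
    if (length(a$markers)) x$markers <- as.list(a$markers)
    if (a$point_mutation) x$point_mutation <- TRUE
    if (length(a$deletes_sites)) x$deletes_sites <- as.list(a$deletes_sites)
    if (a$low_confidence) x$low_confidence <- TRUE
    x$rank <- a$rank
    x
  })
  tg <- lapply(seq_len(nrow(panel$targets)), function(i) {
    r <- panel$targets[i, ]
    x <- list(name = r$name, dye = r$dye, expected_size = r$expected_size,
              role = r$role)
    if (!is.na(r$variant_link)) x$variant_link <- r$variant_link
    x
  })
  doc <- list(version = panel$version, targets = tg, alleles = al,
              thresholds = list(
                min_same_dye_spacing = panel$min_same_dye_spacing,
                size_tolerance = panel$size_tolerance,
                analytical_min_height = panel$analytical_min_height),
              ladder_sizes = as.list(panel$ladder_sizes))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a panel definition from YAML
#'
#' @param path Panel YAML file (see [write_panel()] for the schema).
#' @return A `thal_panel`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  doc <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop(structure(class = c("thal_panel_structure_error", "error",
                             "condition"),
                   list(message = paste0("unparseable panel: ",
                                         conditionMessage(e)), call = NULL))))
  if (!is.list(doc) || is.null(doc$targets) || is.null(doc$alleles))
    stop(structure(class = c("thal_panel_structure_error", "error",
                             "condition"),
                   list(message = "panel file lacks targets/alleles sections",
                        call = NULL)))
  tg <- do.call(rbind, lapply(doc$targets, function(t)
    amplicon_target(t$name, t$dye, t$expected_size, t$role,
                    if (is.null(t$variant_link)) NA_character_
                    else t$variant_link)))
  al <- lapply(names(doc$alleles), function(n) {
    a <- doc$alleles[[n]]
    allele_def(n, a$cluster,
               copies = if (is.null(a$copies)) NULL else unlist(a$copies),
               markers = as.character(unlist(a$markers)),
               point_mutation = isTRUE(a$point_mutation),
               deletes_sites = as.character(unlist(a$deletes_sites)),
               low_confidence = isTRUE(a$low_confidence),
               rank = if (is.null(a$rank)) 50L else as.integer(a$rank))
  })
  th <- doc$thresholds
  new_panel(tg, al,
            min_same_dye_spacing = th$min_same_dye_spacing %||% 3,
            size_tolerance = th$size_tolerance %||% 1.4,
            analytical_min_height = th$analytical_min_height %||% 200,
            ladder_sizes = if (is.null(doc$ladder_sizes))
              default_ladder_sizes() else unlist(doc$ladder_sizes),
            version = doc$version %||% "unversioned")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.thal_panel <- function(x, ...) {
  cat("<thal_panel>", x$version, "\n")
  cat("  targets:", nrow(x$targets), "(",
      paste(sprintf("%s=%d", names(table(x$targets$dye)),
                    as.integer(table(x$targets$dye))), collapse = ", "),
      ")\n")
  cl <- vapply(x$alleles, `[[`, character(1), "cluster")
  cat("  alleles:", sum(cl == "alpha"), "alpha,", sum(cl == "beta"),
      "beta\n")
  cat("  ratio classes:", nrow(x$ratio_classes),
      sprintf("(%d validated)\n", sum(x$ratio_classes$validated)))
  invisible(x)
}
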