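# Region-level still-face contrast: collapse the 12 x 12 channel-pair
# matrices into 5 x 5 inter-brain region pairs and test SF < FP/RU one-sided
# with FDR over the 50 tests (5 x 5 regions x 2 bands).

#' Electrode-to-region map for the topographical analysis
#'
#' Default five regions: frontal (F7, F8), central-parietal (C3, C4),
#' occipital (P7, P8), left temporal (T7), right temporal (T8). F3, F4, P3
#' and P4 are left unassigned by default — the grouping follows the published
#' five-region list — but the map is fully configurable.
#'
#' @param regions named list mapping region name to electrode labels.
#' @return the validated map (class `region_map`).
#' @export
region_map <- function(regions = list(
  frontal = c("F7", "F8"),
  central_parietal = c("C3", "C4"),
  occipital = c("P7", "P8"),
  left_temporal = "T7",
  right_temporal = "T8")) {
  labs <- unlist(regions, use.names = FALSE)
  if (anyDuplicated(labs))
    stop("regions must be disjoint; duplicated: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  unknown <- setdiff(labs, analysis_channels())
  if (length(unknown))
    stop("electrodes not in the 12-channel montage: ",
         paste(unknown, collapse = ", "))
  structure(regions, class = "region_map")
}

#' Per-dyad region x region synchrony for a condition group
#'
#' For each dyad: averages the trial-averaged 12 x 12 pair matrices over the
#' conditions in the group (unweighted mean of condition means), then
#' averages over all electrode combinations within each (infant region,
#' mother region) cell. Averaging order is conditions first, then electrode
#' pairs.
#'
#' @param st stacked `synchrony_table` rows (several dyads, one band), e.g.
#'   `do.call(rbind, cohort_tables)` filtered to one band.
#' @param map a [region_map()].
#' @param condition_group character vector of condition labels to combine.
#' @return 3-d array dyads x infant regions x mother regions.
#' @export
region_pair_values <- function(st, map, condition_group) {
  stopifnot(inherits(map, "region_map"))
  if (length(unique(st$band)) != 1) stop("one band at a time")
  ids <- unique(st$dyad_id)
  rg <- names(map)
  out <- array(NA_real_, c(length(ids), length(rg), length(rg)),
               dimnames = list(ids, rg, rg))
  for (d in seq_along(ids)) {
    sel <- which(st$dyad_id == ids[d] & st$condition %in% condition_group)
    if (length(sel) != length(condition_group))
      stop("dyad ", ids[d], " is missing conditions from the group")
    m <- Reduce(`+`, st$pair_matrix[sel]) / length(sel)  # mother x infant
    for (ir in rg) for (mr in rg)
      out[d, ir, mr] <- mean(m[map[[mr]], map[[ir]]])
  }
  out
}

#' One-sided still-face contrast over inter-brain region pairs
#'
#' Per band, for each of the 25 (infant region x mother region) cells: a
#' paired t-test across dyads of the combined still-face value (mean of SF1,
#' SF2) against the combined free-play/reunion value (mean of FP1, FP2, RU),
#' one-sided with the alternative "less" (synchrony lower during
#' still-face). Benjamini-Hochberg FDR is applied over all 50 tests (both
#' bands, one family) by default; `fdr_family = "band"` corrects per band.
#' Zero-variance difference cells are reported as degenerate with t = 0 and
#' p = 1.
#'
#' @param st stacked `synchrony_table` rows for the cohort (both bands).
#' @param map a [region_map()].
#' @param sf_conditions still-face condition labels (default SF1, SF2).
#' @param ref_conditions comparison labels (default FP1, FP2, RU).
#' @param fdr_family `"all"` (default) or `"band"`.
#' @return data.frame with one row per (band, infant_region, mother_region):
#'   `t`, `df`, `p_raw`, `p_fdr`, `direction = "less"`.
#' @export
still_face_contrast <- function(st, map = region_map(),
                                sf_conditions = c("SF1", "SF2"),
                                ref_conditions = c("FP1", "FP2", "RU"),
                                fdr_family = c("all", "band")) {
  fdr_family <- match.arg(fdr_family)
  rows <- list()
  for (b in unique(st$band)) {
    sb <- st[st$band == b, , drop = FALSE]
    sf <- region_pair_values(sb, map, sf_conditions)
    fr <- region_pair_values(sb, map, ref_conditions)
    if (dim(sf)[1] < 3) stop("fewer than 3 dyads with both condition groups")
    rg <- names(map)
    for (ir in rg) for (mr in rg) {
      d <- sf[, ir, mr] - fr[, ir, mr]
      d <- d[!is.na(d)]
      tol <- 1e-12 * mean(abs(sf[, ir, mr]) + abs(fr[, ir, mr]), na.rm = TRUE)
      d[abs(d) <= tol] <- 0
      if (length(d) >= 3 && sd(d) == 0 && mean(d) == 0) {
        # identical condition groups: t = 0, one-sided p = 1/2
        tt <- list(statistic = 0, parameter = length(d) - 1, p.value = 0.5)
      } else if (length(d) < 3 || sd(d) == 0) {
        # zero-variance differences: degenerate, report conservatively
        tt <- list(statistic = 0, parameter = length(d) - 1, p.value = 1)
      } else {
        tt <- t.test(d, alternative = "less")
      }
      rows <- c(rows, list(data.frame(
        band = b, infant_region = ir, mother_region = mr,
        t = unname(tt$statistic), df = unname(tt$parameter),
        p_raw = tt$p.value, direction = "less", n = length(d))))
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- if (fdr_family == "all") p.adjust(out$p_raw, method = "BH")
               else stats::ave(out$p_raw, out$band,
                               FUN = function(p) p.adjust(p, method = "BH"))
  out
}
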