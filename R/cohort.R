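# Cohort-level simulation: participants measured twice per scanner on two
# scanners, with explicit between-participant and between-session variance
# components on the tract metrics, so the true intraclass correlation of
# every metric is known by construction:
#   ICC_single = sd_between^2 / (sd_between^2 + sd_session^2).

#' Cohort specification for a test-retest / inter-scanner study
#'
#' @param n_participants number of participants (>= 2; the study design
#'   uses 16).
#' @param sessions_per_scanner repeated sessions per scanner (default 2).
#' @param scanners named list of scanners; each element is a named numeric
#'   vector of fixed additive offsets per metric (use `numeric(0)` or 0
#'   for none).
#' @param between_participant_sd named list metric -> SD of the
#'   participant-level (stable) deviation, applied to every region, or a
#'   region-named vector per metric.
#' @param between_session_sd named list metric -> SD of the session-level
#'   (error) deviation, same shapes.
#' @param metric_floor lower clamp for perturbed diffusivity metrics;
#'   values at or below 0 are clamped here with a warning.
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 16L,
                        sessions_per_scanner = 2L,
                        scanners = list(ScannerA = c(), ScannerB = c()),
                        between_participant_sd = list(FA = 0.022, RD = 0.047,
                                                      MD = 0.029, AD = 0.125),
                        between_session_sd = list(FA = 0.008, RD = 0.025,
                                                  MD = 0.030, AD = 0.055),
                        metric_floor = 1e-3,
                        seed = 1L) {
  if (n_participants < 2) stopf("n_participants must be >= 2")
  chk <- function(lst, what) {
    for (m in names(lst)) if (any(unlist(lst[[m]]) < 0))
      stopf("%s for metric %s must be >= 0", what, m)
  }
  chk(between_participant_sd, "between_participant_sd")
  chk(between_session_sd, "between_session_sd")
  structure(list(n_participants = as.integer(n_participants),
                 sessions_per_scanner = as.integer(sessions_per_scanner),
                 scanners = scanners,
                 between_participant_sd = between_participant_sd,
                 between_session_sd = between_session_sd,
                 metric_floor = metric_floor, seed = seed),
            class = "cohort_spec")
}

sd_for <- function(sds, metric, region) {
  s <- sds[[metric]]
  if (is.null(s)) return(0)
  if (length(s) > 1 && !is.null(names(s))) return(unname(s[region]) %||% 0)
  unname(s)
}

#' Simulate a test-retest / inter-scanner cohort
#'
#' For every participant a stable deviation per region x metric is drawn
#' once (between-participant SD, shared across scanners and sessions);
#' every scanner x session adds an independent session deviation
#' (between-session SD) plus the scanner's fixed offset.  The truth table
#' records the realized per-session true region metrics.  With
#' `images = TRUE` a DWI stack is synthesized per participant x scanner x
#' session from tensors rebuilt from the realized (AD, RD) pair
#' (axially symmetric, l1 = AD, l2 = l3 = RD); in that mode the FA and MD
#' rows of the truth table are recomputed analytically from the rebuilt
#' tensor so that truth and image are always consistent.
#'
#' @param cohort a [cohort_spec()].
#' @param phantom a [phantom_spec()] providing the base region tensors and
#'   (for `images = TRUE`) the imaging conditions.
#' @param scheme a [diffusion_scheme()] used when synthesizing images.
#' @param images synthesize DWI stacks (slow) or only the truth table.
#' @param regions regions carried in the truth table.
#' @return List with `truth` (tidy data frame: participant, scanner,
#'   session, region, metric, value) and `stacks` (nested list keyed
#'   `participant.scanner.session`, `NULL` unless `images = TRUE`).
#' @export
simulate_cohort <- function(cohort, phantom = phantom_spec(),
                            scheme = diffusion_scheme(), images = FALSE,
                            regions = c("PT", "DC", "AH")) {
  metrics <- c("FA", "MD", "AD", "RD")
  base <- sapply(regions, function(rg) {
    ev <- phantom$region_tensors[[rg]]
    metrics_from_eigenvalues(ev[1], ev[2], ev[3])[metrics]
  })  # metrics x regions
  rownames(base) <- metrics
  scanners <- names(cohort$scanners)
  sessions <- seq_len(cohort$sessions_per_scanner)
  n_clamped <- 0L
  rows <- list()
  stacks <- if (images) list() else NULL
  with_seed(cohort$seed, {
    for (p in seq_len(cohort$n_participants)) {
      pid <- sprintf("P%02d", p)
      pdev <- sapply(regions, function(rg) vapply(metrics, function(m)
        rnorm(1, 0, sd_for(cohort$between_participant_sd, m, rg)), numeric(1)))
      for (sc in scanners) {
        off <- cohort$scanners[[sc]]
        for (ss in sessions) {
          sdev <- sapply(regions, function(rg) vapply(metrics, function(m)
            rnorm(1, 0, sd_for(cohort$between_session_sd, m, rg)), numeric(1)))
          val <- base + pdev + sdev
          for (m in names(off)) val[m, ] <- val[m, ] + off[[m]]
          low <- val <= 0
          n_clamped <- n_clamped + sum(low)
          val[low] <- cohort$metric_floor
          if (images) {
            tensors <- phantom$region_tensors
            for (rg in regions) {
              ad <- val["AD", rg]; rd <- val["RD", rg]
              if (ad < rd) { tmp <- ad; ad <- rd; rd <- tmp }
              tensors[[rg]] <- c(ad, rd, rd)
              mm <- metrics_from_eigenvalues(ad, rd, rd)
              val["FA", rg] <- mm[["FA"]]; val["MD", rg] <- mm[["MD"]]
              val["AD", rg] <- ad; val["RD", rg] <- rd
            }
            ph <- phantom
            ph$region_tensors <- tensors
            ph$seed <- cohort$seed + 7919L * p + 101L * match(sc, scanners) + ss
            stacks[[sprintf("%s.%s.s%d", pid, sc, ss)]] <-
              generate_phantom(ph, scheme)
          }
          for (rg in regions) for (m in metrics) {
            rows[[length(rows) + 1]] <- data.frame(
              participant = pid, scanner = sc, session = ss,
              region = rg, metric = m, value = val[m, rg])
          }
        }
      }
    }
  })
  if (n_clamped > 0)
    warnf("%d perturbed metric value(s) were non-positive and clamped to %.g",
          n_clamped, cohort$metric_floor)
  list(truth = do.call(rbind, rows), stacks = stacks)
}
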