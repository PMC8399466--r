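# Repeated-measures ANOVA wrapper around car::Anova (type III, multivariate
# lm with an idesign), returning a flat effect table with Greenhouse-Geisser
# adjusted p-values for effects with more than one numerator df.

rm_anova <- function(data, dv, subject, within, alpha = 0.05) {
  for (f in c(subject, within)) data[[f]] <- factor(data[[f]])
  cells <- do.call(interaction, c(data[within], drop = FALSE, sep = "."))
  agg <- stats::aggregate(data[[dv]], list(subject = data[[subject]], cell = cells), mean)
  wide <- stats::reshape(agg, idvar = "subject", timevar = "cell", direction = "wide")
  if (anyNA(wide)) stop_named("missing_cells", "incomplete design: missing cells (no imputation)")
  m <- as.matrix(wide[, -1, drop = FALSE])
  cell_levels <- sub("^x\\.", "", colnames(wide)[-1])
  idata <- do.call(rbind, lapply(strsplit(cell_levels, ".", fixed = TRUE), function(p) {
    stats::setNames(as.data.frame(as.list(p), stringsAsFactors = FALSE), within)
  }))
  for (f in within) idata[[f]] <- factor(idata[[f]], levels = unique(idata[[f]]))
  if (all(abs(m - m[1]) < 1e-12)) {
    return(structure(list(effects = data.frame(
      effect = character(), df1 = numeric(), df2 = numeric(), F = numeric(),
      p = numeric(), gg_eps = numeric(), p_gg = numeric(), significant = logical()),
      degenerate = TRUE, alpha = alpha), class = "rm_anova"))
  }
  mod <- stats::lm(m ~ 1)
  av <- car::Anova(mod, idata = idata,
                   idesign = stats::as.formula(paste("~", paste(within, collapse = "*"))),
                   type = "III")
  sm <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- sm$univariate.tests
  eff <- setdiff(rownames(ut), "(Intercept)")
  tab <- data.frame(
    effect = eff,
    df1 = ut[eff, "num Df"],
    df2 = ut[eff, "den Df"],
    F = ut[eff, "F value"],
    p = ut[eff, "Pr(>F)"],
    gg_eps = NA_real_, p_gg = NA_real_,
    stringsAsFactors = FALSE
  )
  pa <- sm$pval.adjustments
  if (!is.null(pa) && nrow(pa)) {
    hit <- intersect(rownames(pa), eff)
    tab$gg_eps[match(hit, tab$effect)] <- pa[hit, "GG eps"]
    tab$p_gg[match(hit, tab$effect)] <- pa[hit, "Pr(>F[GG])"]
  }
  # sphericity correction only matters for >1-df effects; report the
  # corrected p there, the uncorrected one otherwise
  tab$p_report <- ifelse(!is.na(tab$p_gg) & tab$df1 > 1, tab$p_gg, tab$p)
  tab$significant <- tab$p_report < alpha
  rownames(tab) <- NULL
  structure(list(effects = tab, degenerate = FALSE, alpha = alpha), class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  if (x$degenerate) {
    cat("Repeated-measures ANOVA: constant data, F undefined (degenerate)\n")
    return(invisible(x))
  }
  cat(sprintf("Repeated-measures ANOVA (alpha = %g)\n", x$alpha))
  tab <- x$effects
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-28s F(%g, %g) = %.3f, p = %.4g%s%s\n",
                tab$effect[i], tab$df1[i], tab$df2[i], tab$F[i], tab$p_report[i],
                if (!is.na(tab$gg_eps[i]) && tab$df1[i] > 1)
                  sprintf(" (GG eps = %.3f)", tab$gg_eps[i]) else "",
                if (tab$significant[i]) " *" else ""))
  }
  invisible(x)
}

#' Endpoint mean / variability ANOVAs
#'
#' Runs the 2 (object) x 2 (contrast) x 4 (saccade number, saccades 2-5)
#' repeated-measures ANOVA for each of four dependent measures: mean
#' horizontal endpoint, mean vertical endpoint, and horizontal / vertical
#' endpoint variability (the within-cell SD across trials, per participant).
#' p-values are compared against a multiple-testing-corrected alpha of
#' 0.0125 (0.05 / 4 measures); Greenhouse-Geisser correction applies to
#' effects involving the 4-level saccade-number factor.
#'
#' @param cells data.frame with one row per participant x object x contrast
#'   x saccade_number cell and columns `participant_id, object, contrast,
#'   saccade_number, mean_x, mean_y, sd_x, sd_y` (see
#'   [endpoint_cell_stats()]).
#' @param alpha corrected alpha level.
#' @param posthoc if TRUE, adds paired t-tests between contrast levels per
#'   object x saccade_number cell for each measure.
#' @return named list of `rm_anova` objects (one per measure), plus
#'   `posthoc` when requested.
#' @export
endpoint_anova <- function(cells, alpha = 0.0125, posthoc = FALSE) {
  within <- c("object", "contrast", "saccade_number")
  out <- lapply(c(mean_x = "mean_x", mean_y = "mean_y",
                  sd_x = "sd_x", sd_y = "sd_y"),
                function(dv) rm_anova(cells, dv, "participant_id", within, alpha))
  if (posthoc) {
    out$posthoc <- do.call(rbind, lapply(c("mean_x", "mean_y", "sd_x", "sd_y"), function(dv) {
      do.call(rbind, lapply(split(cells, list(cells$object, cells$saccade_number), drop = TRUE),
        function(cc) {
          wideL <- cc[cc$contrast == "low", ]
          wideH <- cc[cc$contrast == "high", ]
          wideH <- wideH[match(wideL$participant_id, wideH$participant_id), ]
          tt <- stats::t.test(wideL[[dv]], wideH[[dv]], paired = TRUE)
          data.frame(measure = dv, object = cc$object[1],
                     saccade_number = cc$saccade_number[1],
                     t = unname(tt$statistic), df = unname(tt$parameter),
                     p = tt$p.value, stringsAsFactors = FALSE)
        }))
    }))
    rownames(out$posthoc) <- NULL
  }
  out
}

#' Per-cell endpoint statistics for the variability ANOVAs
#'
#' Collapses trial-level saccade endpoints to one row per participant x
#' object x contrast x saccade-number cell: mean and SD of the horizontal
#' and vertical endpoint across trials.
#'
#' @param endpoints data.frame with `participant_id, object, contrast,
#'   saccade_number, endpoint_x, endpoint_y` (one row per saccade).
#' @param saccade_numbers which ordinals to keep (2-5 by default; primary
#'   saccades are excluded because their endpoints confound with latency).
#' @return cell-level data.frame for [endpoint_anova()].
#' @export
endpoint_cell_stats <- function(endpoints, saccade_numbers = 2:5) {
  e <- endpoints[endpoints$saccade_number %in% saccade_numbers, , drop = FALSE]
  key <- list(participant_id = e$participant_id, object = e$object,
              contrast = e$contrast, saccade_number = e$saccade_number)
  agg <- function(v, f) stats::aggregate(v, key, f)
  mx <- agg(e$endpoint_x, mean); my <- agg(e$endpoint_y, mean)
  sx <- agg(e$endpoint_x, stats::sd); sy <- agg(e$endpoint_y, stats::sd)
  out <- mx; names(out)[names(out) == "x"] <- "mean_x"
  out$mean_y <- my$x; out$sd_x <- sx$x; out$sd_y <- sy$x
  out
}

#' Latency / fixation-duration ANOVA
#'
#' The 2 (object: present vs absent) x 2 (contrast: low vs high)
#' repeated-measures ANOVA on per-participant cell means, used for primary
#' saccade latencies (anticipatory saccades removed beforehand) and for the
#' fixation duration between primary and secondary saccade.
#'
#' @param cells data.frame `participant_id, object, contrast, value` with
#'   one row per cell.
#' @param alpha alpha level.
#' @return an `rm_anova` object.
#' @export
latency_anova <- function(cells, alpha = 0.05) {
  rm_anova(cells, "value", "participant_id", c("object", "contrast"), alpha)
}

#' Wilcoxon signed-rank test for anticipatory-saccade frequencies
#'
#' Paired comparison of the per-participant fraction of anticipatory
#' saccades between two conditions, using the same signed-rank conventions
#' as [group_comparison()].
#'
#' @param frac_a,frac_b paired per-participant fractions.
#' @return list `V, Z, p, method`.
#' @export
anticipatory_test <- function(frac_a, frac_b) {
  res <- group_comparison(frac_a, frac_b)
  res[c("V", "Z", "p", "method")]
}
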