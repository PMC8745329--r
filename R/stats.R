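# Replicate averaging, univariate 0-10 scaling, paired t-tests and
# significance-filtered subtraction heatmaps.

.PARAM_COLS <- paste0("P", 1:7)
.KEY_COLS <- c("donor", "replicate", "surface", "preset", "switch_time",
               "timepoint")

# Condition label used in heatmap columns and file names.
.cond_label <- function(preset, switch_time) {
  ifelse(preset == "vehicle", "vehicle",
         paste0(preset, "@", ifelse(is.na(switch_time), "never", switch_time)))
}

#' Average replicate flow runs per donor
#'
#' Collapses duplicate/triplicate flow runs of the same donor into one
#' parameter set per donor, condition, surface and time point (arithmetic
#' mean of P1-P7).
#'
#' @param records data.frame with key columns `donor`, `replicate`,
#'   `surface`, `preset`, `switch_time`, `timepoint` and parameter columns
#'   `P1`..`P7`.
#'
#' @return data.frame with one row per (donor, surface, preset, switch_time,
#'   timepoint) and averaged `P1`..`P7`; no `replicate` column.
#' @export
#' @examples
#' recs <- data.frame(donor = "d1", replicate = c("r1", "r2"),
#'                    surface = "collagen", preset = "vehicle",
#'                    switch_time = NA, timepoint = 2,
#'                    P1 = c(10, 20), P2 = 0, P3 = 0, P4 = 0, P5 = 0,
#'                    P6 = 0, P7 = 0)
#' average_replicates(recs)$P1  # 15
average_replicates <- function(records) {
  need <- c(.KEY_COLS, .PARAM_COLS)
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(records) == 0)
    stop("missing cells: no records to average")
  keys <- setdiff(.KEY_COLS, "replicate")
  grp <- records[keys]
  grp$switch_time <- ifelse(is.na(grp$switch_time), "never",
                            as.character(grp$switch_time))
  agg <- aggregate(records[.PARAM_COLS], by = grp, FUN = mean)
  agg$switch_time <- suppressWarnings(as.numeric(agg$switch_time))
  agg[order(agg$surface, agg$preset, agg$switch_time, agg$donor,
            agg$timepoint), , drop = FALSE]
}

#' Univariate 0-10 scaling
#'
#' Affine rescaling of a parameter series onto the range 0-10:
#' `x -> 10 * (x - min) / (max - min)`. The series minimum maps to 0 and the
#' maximum to 10. A constant series carries no contrast and maps to all
#' zeros, with a warning.
#'
#' @param x Numeric vector (one parameter across all conditions, surfaces
#'   and time points of an experiment set).
#'
#' @return Scaled numeric vector with attribute `bounds = c(min, max)`.
#' @export
#' @examples
#' univariate_scale(c(2, 4, 6))  # 0 5 10
univariate_scale <- function(x) {
  if (length(x) == 0) stop("cannot scale an empty series")
  if (!is.numeric(x)) stop("series must be numeric")
  lo <- min(x); hi <- max(x)
  if (hi - lo <= 0) {
    warning("constant series: scaled to all zeros")
    out <- rep(0, length(x))
  } else {
    out <- 10 * (x - lo) / (hi - lo)
  }
  attr(out, "bounds") <- c(min = lo, max = hi)
  out
}

#' Scale donor-averaged parameter records to 0-10
#'
#' Applies [univariate_scale()] per parameter. By default the scaling pools
#' all conditions, surfaces and time points of the experiment set, so that
#' heatmap panels are comparable across surfaces; `scope = "surface"` scales
#' each surface separately.
#'
#' @param donor_records Donor-averaged records from [average_replicates()].
#' @param scope `"all"` (default) or `"surface"`.
#'
#' @return A list of class `scaled_records`: `records` (input with P1..P7
#'   replaced by scaled values), `bounds` (parameter x (min, max) matrix per
#'   scaling group) and `n_donors`.
#' @export
scale_records <- function(donor_records, scope = c("all", "surface")) {
  scope <- match.arg(scope)
  out <- donor_records
  groups <- if (scope == "all") list(all = seq_len(nrow(out)))
            else split(seq_len(nrow(out)), out$surface)
  bounds <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    for (p in .PARAM_COLS) {
      sc <- withCallingHandlers(
        univariate_scale(out[[p]][idx]),
        warning = function(w) invokeRestart("muffleWarning"))
      out[[p]][idx] <- as.numeric(sc)
      bounds[[paste(g, p, sep = ".")]] <- attr(sc, "bounds")
    }
  }
  structure(list(records = out, bounds = bounds,
                 n_donors = length(unique(out$donor)), scope = scope),
            class = "scaled_records")
}

#' Paired Student's t-test
#'
#' Two-sided paired t-test on donor-aligned control and treated values:
#' `d = treated - control`, `t = mean(d) / (sd(d) / sqrt(n))` with the
#' sample standard deviation (n - 1 denominator), `df = n - 1`.
#'
#' Degenerate cases: with `sd(d) = 0` and a non-zero mean difference the
#' statistic is infinite and p is 0 (a warning flags the degenerate
#' variance); with all differences exactly zero, t = 0 and p = 1.
#'
#' @param control,treated Numeric vectors of equal length n >= 2, element i
#'   belonging to donor i in both.
#'
#' @return List with elements `t`, `df`, `p`.
#' @export
#' @examples
#' paired_t_test(c(0, 0, 0, 0, 0), c(1, 2, 3, 4, 5))
paired_t_test <- function(control, treated) {
  if (length(control) != length(treated))
    stop("control and treated must be donor-aligned vectors of equal length")
  n <- length(control)
  if (n < 2) stop("paired t-test requires at least 2 donors")
  d <- treated - control
  s <- sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(list(t = 0, df = n - 1, p = 1))
    warning("degenerate variance: all paired differences identical")
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0))
  }
  tstat <- mean(d) / (s / sqrt(n))
  list(t = tstat, df = n - 1, p = 2 * pt(-abs(tstat), df = n - 1))
}

#' Subtraction heatmap with significance filter
#'
#' Cell-wise difference of scaled treated and reference matrices, optionally
#' zeroing cells whose paired t-test p-value is at or above `alpha` so that
#' only relevant changes remain visible.
#'
#' @param scaled_treated,scaled_reference Numeric matrices with identical
#'   dimnames (parameters x condition/time cells), on the 0-10 scale.
#' @param p_values Matrix of p-values aligned with the grids.
#' @param alpha Significance level (default 0.05).
#' @param filtered If `TRUE` (default), set non-significant cells to 0.
#'
#' @return List of class `subtraction_heatmap` with `delta`, `p_values`,
#'   `alpha`, `filtered`.
#' @export
subtraction_heatmap <- function(scaled_treated, scaled_reference, p_values,
                                alpha = 0.05, filtered = TRUE) {
  if (!identical(dim(scaled_treated), dim(scaled_reference)) ||
      !identical(dimnames(scaled_treated), dimnames(scaled_reference)))
    stop("alignment error: treated and reference grids differ in keys")
  if (!identical(dim(scaled_treated), dim(p_values)))
    stop("alignment error: p-value grid does not match")
  delta <- scaled_treated - scaled_reference
  if (filtered) delta[p_values >= alpha] <- 0
  structure(list(delta = delta, p_values = p_values, alpha = alpha,
                 filtered = filtered),
            class = "subtraction_heatmap")
}

# Wide parameter x (surface|condition|time) matrix of donor means from a
# scaled (or raw) donor-level record table.
.records_to_matrix <- function(records) {
  cells <- unique(records[c("surface", "preset", "switch_time", "timepoint")])
  cells <- cells[order(cells$surface, cells$preset, cells$switch_time,
                       cells$timepoint), , drop = FALSE]
  colnames_out <- paste(cells$surface,
                        .cond_label(cells$preset, cells$switch_time),
                        paste0("t", cells$timepoint), sep = "|")
  m <- matrix(NA_real_, nrow = length(.PARAM_COLS), ncol = nrow(cells),
              dimnames = list(.PARAM_COLS, colnames_out))
  for (j in seq_len(nrow(cells))) {
    sel <- records$surface == cells$surface[j] &
      records$preset == cells$preset[j] &
      (records$switch_time %in% cells$switch_time[j] |
         (is.na(records$switch_time) & is.na(cells$switch_time[j]))) &
      records$timepoint == cells$timepoint[j]
    for (p in .PARAM_COLS) m[p, j] <- mean(records[[p]][sel])
  }
  m
}

#' Assemble scaled and subtraction heatmaps with underlying tables
#'
#' Full statistics stage: average replicates per donor, scale to 0-10,
#' write the scaled heatmap (parameters P1-P7 by surface, condition and
#' time point), and for every non-reference condition write a subtraction
#' heatmap versus the reference runs, with per-cell paired t-tests across
#' donors and the p < alpha relevance filter. Deltas and p-values are also
#' written as CSV tables; the unfiltered delta is always retained in the
#' CSV.
#'
#' @param records Raw parameter records (one row per run and time point).
#' @param out_dir Output directory (created if missing).
#' @param reference_preset Condition used as reference (default
#'   `"vehicle"`).
#' @param reference_surface If `NULL` (default) each condition is compared
#'   against the reference on its own surface; a surface name compares all
#'   conditions against the reference on that surface.
#' @param alpha Significance level for the relevance filter (default 0.05).
#' @param filtered Apply the filter to the heatmap figures (default TRUE).
#' @param scale_scope Scaling scope, see [scale_records()].
#' @param p_adjust `"none"` (default, per-cell raw p-values) or `"BH"` for
#'   Benjamini-Hochberg adjustment across the cells of each condition.
#' @param figures Write pheatmap PDFs alongside the CSVs (default TRUE).
#'
#' @return Invisibly, a list with `scaled` (matrix), `scaled_records`,
#'   `subtractions` (named list of `subtraction_heatmap`), and the file
#'   paths written.
#' @export
assemble_report <- function(records, out_dir,
                            reference_preset = "vehicle",
                            reference_surface = NULL,
                            alpha = 0.05, filtered = TRUE,
                            scale_scope = "all", p_adjust = c("none", "BH"),
                            figures = TRUE) {
  p_adjust <- match.arg(p_adjust)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  donor_avg <- average_replicates(records)
  scaled <- scale_records(donor_avg, scope = scale_scope)
  srec <- scaled$records

  scaled_matrix <- .records_to_matrix(srec)
  paths <- c(scaled = file.path(out_dir, "scaled.csv"))
  write.csv(data.frame(parameter = rownames(scaled_matrix), scaled_matrix,
                       check.names = FALSE),
            paths[["scaled"]], row.names = FALSE)
  if (figures)
    .write_heatmap_pdf(scaled_matrix, file.path(out_dir, "scaled_heatmap.pdf"),
                       main = "Scaled parameters (0-10)", diverging = FALSE)

  conds <- unique(srec[srec$preset != reference_preset,
                       c("preset", "switch_time")])
  subtractions <- list()
  for (k in seq_len(nrow(conds))) {
    pr <- conds$preset[k]; sw <- conds$switch_time[k]
    label <- .cond_label(pr, sw)
    tre <- srec[srec$preset == pr &
                  (srec$switch_time %in% sw |
                     (is.na(srec$switch_time) & is.na(sw))), , drop = FALSE]
    surfaces <- unique(tre$surface)
    tre_m <- ref_m <- p_m <- NULL
    for (sf in surfaces) {
      ref_sf <- if (is.null(reference_surface)) sf else reference_surface
      ref <- srec[srec$preset == reference_preset &
                    srec$surface == ref_sf, , drop = FALSE]
      tre_sf <- tre[tre$surface == sf, , drop = FALSE]
      tps <- sort(unique(tre_sf$timepoint))
      cn <- paste(sf, label, paste0("t", tps), sep = "|")
      tm <- rm <- pm <- matrix(NA_real_, 7, length(tps),
                               dimnames = list(.PARAM_COLS, cn))
      for (j in seq_along(tps)) {
        donors <- sort(unique(tre_sf$donor))
        for (p in .PARAM_COLS) {
          tv <- vapply(donors, function(d)
            mean(tre_sf[[p]][tre_sf$donor == d & tre_sf$timepoint == tps[j]]),
            numeric(1))
          rv <- vapply(donors, function(d)
            mean(ref[[p]][ref$donor == d & ref$timepoint == tps[j]]),
            numeric(1))
          ok <- is.finite(tv) & is.finite(rv)
          if (sum(ok) < 2)
            stop("missing cells: paired donors < 2 for ", label, " ", sf,
                 " t", tps[j])
          tt <- suppressWarnings(paired_t_test(rv[ok], tv[ok]))
          tm[p, j] <- mean(tv[ok]); rm[p, j] <- mean(rv[ok]); pm[p, j] <- tt$p
        }
      }
      tre_m <- cbind(tre_m, tm); ref_m <- cbind(ref_m, rm)
      p_m <- cbind(p_m, pm)
    }
    if (p_adjust == "BH")
      p_m[] <- p.adjust(p_m, method = "BH")
    sh <- subtraction_heatmap(tre_m, ref_m, p_m, alpha = alpha,
                              filtered = filtered)
    subtractions[[label]] <- sh
    fn <- gsub("@", "_", label)
    delta_path <- file.path(out_dir, paste0("delta_", fn, ".csv"))
    write.csv(data.frame(parameter = .PARAM_COLS,
                         unfiltered_delta = I(tre_m - ref_m),
                         p_value = I(p_m), filtered_delta = I(sh$delta),
                         check.names = FALSE),
              delta_path, row.names = FALSE)
    paths[paste0("delta_", fn)] <- delta_path
    if (figures)
      .write_heatmap_pdf(sh$delta,
                         file.path(out_dir, paste0("delta_", fn, ".pdf")),
                         main = paste("Subtraction:", label,
                                      if (filtered) "(p-filtered)" else ""),
                         diverging = TRUE)
  }
  invisible(list(scaled = scaled_matrix, scaled_records = scaled,
                 subtractions = subtractions, paths = paths))
}

.write_heatmap_pdf <- function(m, path, main = "", diverging = FALSE) {
  cols <- if (diverging)
    grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(101)
  else
    grDevices::colorRampPalette(c("#FFFFCC", "#FD8D3C", "#800026"))(101)
  brk <- if (diverging) seq(-10, 10, length.out = 102)
         else seq(0, 10, length.out = 102)
  pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                     color = cols, breaks = brk, main = main,
                     filename = path, width = max(6, 1 + 0.25 * ncol(m)),
                     height = 3.5, silent = TRUE)
  invisible(path)
}
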