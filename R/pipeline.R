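#' Full morphological analysis of one tumor
#'
#' Orchestrates the per-tumor pipeline: (optional) DQC segmentation of an
#' intensity volume, interface extraction, cylindrical parameterization,
#' box-counting dimension and lacunarity, interface-width scaling,
#' regularity measures, slice-wise visibility-graph statistics, and 1D/2D
#' multifractal analysis. Any stage failure is recorded under \code{qc}
#' and dependent stages are skipped; the record is still returned.
#'
#' @param input either an integer label array (analysis starts at interface
#'   extraction) or an intensity array with \code{segment = TRUE}.
#' @param tumor_id identifier stored in the record.
#' @param group_label optional cohort group tag.
#' @param segment run [dqc_segment()] first and take the brightest class as
#'   tumor (default FALSE: input is already labeled).
#' @param tumor_label,contrast_label,spacing as in [extract_interface()] /
#'   [surface_measures()].
#' @param min_points interface size threshold (default 2000).
#' @param phi_bins,z_bins parameterization resolution.
#' @param mf_q q grid for the multifractal stages.
#' @return a \code{tumor_record} list with elements \code{tumor_id},
#'   \code{group_label}, \code{scaling} (d_F, lacunarity, alpha_loc, W_sat,
#'   R_mean, fv_sum and the fits), \code{regularity}, \code{visibility}
#'   (gamma, a), \code{mf_1d}, \code{mf_2d}, \code{qc}.
#' @export
run_pipeline <- function(input, tumor_id = "tumor", group_label = NA_character_,
                         segment = FALSE, tumor_label = c(1L, 2L),
                         contrast_label = NULL, spacing = c(1, 1, 1),
                         min_points = 2000L, phi_bins = NULL, z_bins = NULL,
                         mf_q = seq(-4, 4, by = 0.5)) {
  qc <- list()
  rec <- list(tumor_id = tumor_id, group_label = group_label)
  labels <- input
  if (segment) {
    seg <- try(dqc_segment(input), silent = TRUE)
    if (inherits(seg, "try-error")) {
      qc$segmentation <- as.character(seg)
      rec$qc <- qc
      return(structure(rec, class = "tumor_record"))
    }
    k <- seg$result$n_classes
    labels <- array(0L, dim = dim(input))
    labels[seg$labels == k] <- 1L   # brightest class = contrast-enhancing
    tumor_label <- 1L; contrast_label <- NULL
    rec$segmentation <- list(n_classes = k, centroids = seg$result$centroids)
  }
  iface <- try(extract_interface(labels, tumor_label, min_points, spacing),
               silent = TRUE)
  if (inherits(iface, "try-error")) {
    qc$interface <- as.character(iface)
    rec$qc <- qc
    return(structure(rec, class = "tumor_record"))
  }
  qc$n_points <- iface$n_points
  qc$rejected <- iface$rejected
  grid <- try(parameterize_interface(iface, phi_bins, z_bins), silent = TRUE)

  # -- scaling ----------------------------------------------------------
  rec$scaling <- tryCatch({
    bf <- box_count(iface$points)
    lac <- lacunarity(iface$points,
                      epsilons = pmax(2L, unique(round(
                        exp(seq(log(2), log(max(3, floor(min(dim(labels)) / 8))),
                                length.out = 5))))))
    sc <- list(d_F = bf$exponent, d_F_fit = bf,
               lacunarity = mean(lac$lambda, na.rm = TRUE),
               lacunarity_table = lac)
    if (!inherits(grid, "try-error")) {
      Ws <- interface_width(grid)
      al <- local_roughness(Ws)
      sat <- saturation_width(Ws)
      cellmm <- 2 * pi * mean(iface$radii) / grid$phi_bins
      sc$alpha_loc <- al$exponent
      sc$alpha_loc_fit <- al
      sc$W_sat <- sat$W_sat * 1          # widths are radial, already in mm
      sc$W_table <- Ws
      sc$crossover_cells <- sat$crossover
      sc$cell_mm <- cellmm
      fv <- family_vicsek_sum(bf$exponent, al$exponent)
      sc$fv_sum <- fv$fv_sum; sc$fv_deviation <- fv$deviation
    } else qc$parameterization <- as.character(grid)
    sc$R_mean <- mean(iface$radii)
    sc
  }, error = function(e) { qc$scaling <<- conditionMessage(e); NULL })

  # -- regularity -------------------------------------------------------
  rec$regularity <- tryCatch(
    regularity_measures(labels, tumor_label, contrast_label, spacing,
                        interface = iface),
    error = function(e) { qc$regularity <<- conditionMessage(e); NULL })
  if (!is.null(rec$regularity)) qc$FA <- rec$regularity$FA

  # -- visibility -------------------------------------------------------
  rec$visibility <- tryCatch({
    os <- ordered_series_from_slice(iface)
    vg <- visibility_graph(os)
    ge <- degree_exponent(vg)
    wk <- local_degree_std(vg, os)
    ve <- tryCatch(variance_exponent(wk), error = function(e) NULL)
    list(gamma = ge$exponent, gamma_fit = ge,
         a = if (is.null(ve)) NA_real_ else ve$exponent,
         a_fit = ve, series = os, degrees = vg$degrees)
  }, error = function(e) { qc$visibility <<- conditionMessage(e); NULL })

  # -- multifractal -----------------------------------------------------
  rec$mf_1d <- tryCatch({
    if (is.null(rec$visibility)) stop("no ordered series")
    mf_partition(rec$visibility$series, q_grid = mf_q)
  }, error = function(e) { qc$mf_1d <<- conditionMessage(e); NULL })
  rec$mf_2d <- tryCatch({
    if (inherits(grid, "try-error")) stop("no interface grid")
    dfa2d(grid, q_grid = mf_q)
  }, error = function(e) { qc$mf_2d <<- conditionMessage(e); NULL })

  rec$qc <- qc
  structure(rec, class = "tumor_record")
}

#' @export
print.tumor_record <- function(x, ...) {
  cat(sprintf("Tumor record '%s'%s\n", x$tumor_id,
              if (!is.na(x$group_label)) paste0(" [", x$group_label, "]") else ""))
  if (!is.null(x$scaling))
    cat(sprintf("  d_F = %.3f  alpha_loc = %.3f  fv_sum = %.3f  W_sat = %.3f  <R> = %.2f\n",
                x$scaling$d_F, x$scaling$alpha_loc %||% NA,
                x$scaling$fv_sum %||% NA, x$scaling$W_sat %||% NA,
                x$scaling$R_mean))
  if (!is.null(x$regularity))
    cat(sprintf("  S_R = %.3f  S_C = %.3f  S_C/S_R = %.3f  FA = %.3f\n",
                x$regularity$S_R, x$regularity$S_C, x$regularity$ratio_SC_SR,
                x$regularity$FA))
  if (!is.null(x$visibility))
    cat(sprintf("  gamma = %.3f  a = %.3f\n", x$visibility$gamma, x$visibility$a))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flatten a tumor record to one row of scalars
#'
#' @param rec a \code{tumor_record}.
#' @return a one-row data.frame of the scalar descriptors.
#' @export
record_row <- function(rec) {
  g <- function(x) if (is.null(x) || length(x) == 0) NA_real_ else as.numeric(x)
  d1 <- function(m, qv) if (is.null(m)) NA_real_ else m$D[which.min(abs(m$q - qv))]
  data.frame(
    tumor_id = rec$tumor_id, group = rec$group_label,
    d_F = g(rec$scaling$d_F), alpha_loc = g(rec$scaling$alpha_loc),
    fv_sum = g(rec$scaling$fv_sum), lacunarity = g(rec$scaling$lacunarity),
    W_sat = g(rec$scaling$W_sat), R_mean = g(rec$scaling$R_mean),
    S_R = g(rec$regularity$S_R), S_C = g(rec$regularity$S_C),
    SC_over_SR = g(rec$regularity$ratio_SC_SR), FA = g(rec$regularity$FA),
    S_R_star = g(rec$regularity$S_R_star),
    gamma = g(rec$visibility$gamma), a = g(rec$visibility$a),
    D1_1 = d1(rec$mf_1d, 1), D1_2 = d1(rec$mf_1d, 2),
    D2_1 = d1(rec$mf_2d, 1), D2_2 = d1(rec$mf_2d, 2),
    n_points = g(rec$qc$n_points),
    stringsAsFactors = FALSE)
}

#' Cohort summary tables
#'
#' Aggregates per-tumor records into per-group mean and SD tables (SD with
#' the n-1 denominator) for every scalar descriptor, and fits the global
#' roughness exponent per group from (W_sat, R_mean). Records failing QC
#' gates (rejected interfaces, FA above the optional threshold) are
#' excluded from the summary but reported.
#'
#' @param records list of \code{tumor_record}s (or a data.frame from
#'   [record_row()]).
#' @param fa_max optional FA gate (default Inf: off).
#' @return list with \code{table} (rows = tumors), \code{summary}
#'   (per-group mean/SD), \code{global_alpha} (per-group powerlaw fits),
#'   \code{excluded}.
#' @export
cohort_summarize <- function(records, fa_max = Inf) {
  tab <- if (is.data.frame(records)) records
  else do.call(rbind, lapply(records, record_row))
  keep <- rep(TRUE, nrow(tab))
  if (is.finite(fa_max)) keep <- keep & (!is.finite(tab$FA) | tab$FA <= fa_max)
  excluded <- tab$tumor_id[!keep]
  use <- tab[keep, , drop = FALSE]
  if (nrow(use) == 0L) stop("cohort_summarize: no records pass QC")
  nums <- setdiff(names(use), c("tumor_id", "group"))
  groups <- split(use, use$group)
  summ <- do.call(rbind, lapply(names(groups), function(gname) {
    gd <- groups[[gname]]
    means <- vapply(nums, function(v) mean(gd[[v]], na.rm = TRUE), numeric(1))
    sds <- vapply(nums, function(v) stats::sd(gd[[v]], na.rm = TRUE), numeric(1))
    data.frame(group = gname, n = nrow(gd), stat = c("mean", "sd"),
               rbind(means, sds), row.names = NULL)
  }))
  galpha <- lapply(groups, function(gd) {
    ok <- is.finite(gd$W_sat) & is.finite(gd$R_mean) & gd$W_sat > 0
    if (sum(ok) >= 5L) global_roughness(gd$W_sat[ok], gd$R_mean[ok]) else NULL
  })
  list(table = tab, summary = summ, global_alpha = galpha,
       excluded = excluded)
}
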