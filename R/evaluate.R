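#' Node-level confusion matrix
#'
#' @param predicted Integer node indices predicted hot.
#' @param truth Integer node indices truly hot.
#' @param n_nodes Total node count N.
#' @return A `confusion_matrix` with counts `TP`, `TN`, `FP`, `FN` and
#'   derived `sensitivity` (TP/(TP+FN), `NA` when no truth nodes exist).
#' @export
confusion <- function(predicted, truth, n_nodes) {
  predicted <- unique(as.integer(predicted))
  truth <- unique(as.integer(truth))
  stop_if_not(all(c(predicted, truth) >= 1) &&
              all(c(predicted, truth) <= n_nodes),
              "node indices out of range")
  tp <- length(intersect(predicted, truth))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  tn <- n_nodes - tp - fp - fn
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("TP %d  FP %d\nFN %d  TN %d  (sensitivity %.3f)\n",
              x$TP, x$FP, x$FN, x$TN, x$sensitivity))
  invisible(x)
}

#' Mean distance from false-positive nodes to the nearest true hot node
#'
#' @param fp_nodes False-positive node indices (may be empty: returns 0).
#' @param truth True hot-node indices (must be nonempty when `fp_nodes` is).
#' @param mesh A `pmi_mesh`.
#' @return Mean Euclidean nearest-truth distance in mm.
#' @export
fp_mean_distance <- function(fp_nodes, truth, mesh) {
  if (!length(fp_nodes)) return(0)
  stop_if_not(length(truth) > 0,
              "false positives given but the truth set is empty")
  fp_xy <- mesh$node_coords[fp_nodes, , drop = FALSE]
  tr_xy <- mesh$node_coords[truth, , drop = FALSE]
  d2 <- outer(rowSums(fp_xy^2), rep(1, nrow(tr_xy))) +
        outer(rep(1, nrow(fp_xy)), rowSums(tr_xy^2)) -
        2 * fp_xy %*% t(tr_xy)
  mean(sqrt(pmax(apply(d2, 1, min), 0)))
}

#' Per-region statistics of a recovered absorption map
#'
#' @param recon_mua Recovered per-node absorption (mm^-1).
#' @param truth_mua True per-node absorption (mm^-1).
#' @param regions Named list of node-index sets (inclusions and optionally
#'   `background`).
#' @param background_nodes Node indices used for the artifact level;
#'   typically background nodes farther than 1 mm from any inclusion.
#' @param inclusion_nodes Union of inclusion node sets.
#' @param reference_mua Known background absorption used as the baseline for
#'   the artifact contrast.
#' @return A `region_stats` data frame (mean, sd, truth, percent error per
#'   region) with attribute `artifact_level`: 100 * max background
#'   recovered contrast / max inclusion recovered contrast (contrast =
#'   recovered - reference background, clamped at 0).
#' @export
region_stats <- function(recon_mua, truth_mua, regions,
                         background_nodes = NULL, inclusion_nodes = NULL,
                         reference_mua = NULL) {
  stop_if_not(length(regions) > 0, "regions must be nonempty")
  stop_if_not(all(lengths(regions) > 0), "empty region")
  df <- do.call(rbind, lapply(seq_along(regions), function(i) {
    idx <- regions[[i]]
    truth <- mean(truth_mua[idx])
    m <- mean(recon_mua[idx])
    data.frame(region = if (!is.null(names(regions))) names(regions)[i]
                        else sprintf("region%d", i),
               mean = m, sd = sd(recon_mua[idx]), truth = truth,
               percent_error = 100 * abs(m - truth) / truth)
  }))
  art <- NA_real_
  if (!is.null(background_nodes) && !is.null(inclusion_nodes)) {
    if (is.null(reference_mua)) reference_mua <- 0
    bg_c <- max(pmax(recon_mua[background_nodes] - reference_mua, 0))
    in_c <- max(pmax(recon_mua[inclusion_nodes] - reference_mua, 0))
    art <- if (in_c > 0) 100 * bg_c / in_c else NA_real_
  }
  attr(df, "artifact_level") <- art
  class(df) <- c("region_stats", class(df))
  df
}

#' Line profile with per-peak FWHM and two-peak resolvability
#'
#' Samples the map bilinearly along a segment, finds local maxima, measures
#' each peak's full width at half maximum by linear interpolation of the
#' half-max crossings, and flags two adjacent peaks resolvable when the
#' valley between them drops below the lower peak's half maximum.
#'
#' @param map A `temperature_map`.
#' @param line 2 x 2 matrix: rows are the (x, y) endpoints in mm.
#' @param n_samples Samples along the segment.
#' @param min_prominence Peaks smaller than this fraction of the profile
#'   maximum are ignored.
#' @return List: `s` (arc positions mm), `values`, `peaks` (data frame with
#'   position, height, fwhm) and `resolvable` (logical, `NA` with fewer
#'   than two peaks).
#' @export
line_profile_fwhm <- function(map, line, n_samples = 512,
                              min_prominence = 0.05) {
  p0 <- line[1, ]; p1 <- line[2, ]
  len <- sqrt(sum((p1 - p0)^2))
  t <- seq(0, 1, length.out = n_samples)
  xy <- cbind(p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]))
  vals <- sample_map_xy(map, xy)
  inmask <- !is.na(vals)
  stop_if_not(any(inmask), "line does not intersect the map mask")
  vals[!inmask] <- 0
  s <- t * len
  vmax <- max(vals)
  peaks <- data.frame(position = numeric(0), height = numeric(0),
                      fwhm = numeric(0), index = integer(0))
  if (vmax > 0) {
    for (i in 2:(n_samples - 1)) {
      if (vals[i] > vals[i - 1] && vals[i] >= vals[i + 1] &&
          vals[i] >= min_prominence * vmax) {
        half <- vals[i] / 2
        li <- i; while (li > 1 && vals[li] > half) li <- li - 1
        ri <- i; while (ri < n_samples && vals[ri] > half) ri <- ri + 1
        sl <- if (vals[li] <= half && li < i) {
          s[li] + (half - vals[li]) / (vals[li + 1] - vals[li]) * (s[li + 1] - s[li])
        } else s[1]
        sr <- if (vals[ri] <= half && ri > i) {
          s[ri - 1] + (vals[ri - 1] - half) / (vals[ri - 1] - vals[ri]) *
            (s[ri] - s[ri - 1])
        } else s[n_samples]
        peaks <- rbind(peaks, data.frame(position = s[i], height = vals[i],
                                         fwhm = sr - sl, index = i))
      }
    }
  }
  resolvable <- NA
  if (nrow(peaks) >= 2) {
    o <- order(peaks$height, decreasing = TRUE)
    two <- peaks[o[1:2], ]
    lo <- min(two$index); hi <- max(two$index)
    valley <- min(vals[lo:hi])
    resolvable <- valley < min(two$height) / 2
  }
  list(s = s, values = vals, peaks = peaks, resolvable = resolvable)
}

# Bilinear sample of a temperature map at arbitrary xy (mm); NA off-mask.
sample_map_xy <- function(map, xy) {
  res <- nrow(map$pixels)
  pc <- pixel_centers(map$extent, res)
  fc <- (xy[, 1] - pc$x[1]) / pc$px + 1
  fr <- (pc$y[1] - xy[, 2]) / pc$py + 1
  ok <- fc >= 1 & fc <= res & fr >= 1 & fr <= res
  out <- rep(NA_real_, nrow(xy))
  if (!any(ok)) return(out)
  c0 <- pmin(pmax(floor(fc[ok]), 1), res - 1)
  r0 <- pmin(pmax(floor(fr[ok]), 1), res - 1)
  wc <- fc[ok] - c0; wr <- fr[ok] - r0
  p <- map$pixels
  v <- (1 - wr) * ((1 - wc) * p[cbind(r0, c0)] + wc * p[cbind(r0, c0 + 1)]) +
       wr * ((1 - wc) * p[cbind(r0 + 1, c0)] + wc * p[cbind(r0 + 1, c0 + 1)])
  inm <- map$mask[cbind(pmin(pmax(round(fr[ok]), 1), res),
                        pmin(pmax(round(fc[ok]), 1), res))]
  v[!inm] <- NA
  out[ok] <- v
  out
}
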