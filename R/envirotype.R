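#' Resample a season's stress trajectory onto centesimal thermal time
#'
#' Interpolates the daily waterSD series against cumulative thermal time
#' normalised to 0-100\%, returning 100 values (at 1\%, ..., 100\%). This
#' puts seasons of different calendar length on a common developmental time
#' axis so their stress patterns can be compared and clustered. Failed
#' seasons have truncated trajectories and are excluded upstream.
#'
#' @param daily_watersd daily waterSD values (crop days).
#' @param daily_tt matching cumulative thermal time (non-decreasing).
#' @return numeric vector of length 100.
#' @export
to_centesimal <- function(daily_watersd, daily_tt) {
  stopifnot(length(daily_watersd) == length(daily_tt),
            !is.unsorted(daily_tt))
  if (max(daily_tt) <= 0) stop("cumulative thermal time must be positive",
                               call. = FALSE)
  x <- daily_tt / max(daily_tt) * 100
  stats::approx(x, daily_watersd, xout = 1:100, rule = 2, ties = "ordered")$y
}

#' Extract the centesimal stress trajectory of a season
#'
#' @param season an `lt_season` from [run_season()]; must be non-failed.
#' @return numeric vector of length 100.
#' @export
stress_trajectory <- function(season) {
  if (isTRUE(season$failed)) {
    stop("failed season: trajectory truncated, excluded from envirotyping",
         call. = FALSE)
  }
  to_centesimal(season$daily$waterSD, season$daily$cum_tt)
}

#' Cluster stress trajectories into water-stress environment types
#'
#' k-medoids with Euclidean distance on the 100-point centesimal
#' trajectories: exhaustive PAM when n <= 500, CLARA subsampling (5 draws
#' of up to 100 + 2k trajectories, seeded) for larger sets. For each k in
#' `k_range` the mean silhouette width over all points is computed; the
#' chosen k maximises it.
#'
#' @param trajectories numeric matrix, one row per season, 100 columns.
#' @param k_range integer candidate numbers of clusters, e.g. `2:8`.
#' @param seed integer seed for the CLARA subsampling.
#' @return an object of class `lt_envclass`: list with `k`, `labels`
#'   (cluster index per row), `medoids` (k x 100 matrix), `silhouette`
#'   (data frame of k vs mean silhouette width) and `names` (filled by
#'   [name_environments()]).
#' @export
cluster_trajectories <- function(trajectories, k_range = 2:8, seed = 1L) {
  trajectories <- as.matrix(trajectories)
  n <- nrow(trajectories)
  k_range <- as.integer(k_range)
  if (any(k_range < 2L) || any(k_range > n - 1L)) {
    stop("k_range must lie within [2, n-1]", call. = FALSE)
  }
  fits <- lapply(k_range, function(k) {
    if (n <= 500) {
      f <- cluster::pam(trajectories, k, metric = "euclidean")
      list(labels = f$clustering, medoids = f$medoids,
           sil = f$silinfo$avg.width)
    } else {
      f <- with_seed(derive_seed(seed, 3001L, k),
                     cluster::clara(trajectories, k, metric = "euclidean",
                                    samples = 5,
                                    sampsize = min(n, 100 + 2 * k),
                                    rngR = TRUE, pamLike = TRUE))
      list(labels = f$clustering, medoids = f$medoids,
           sil = f$silinfo$avg.width)
    }
  })
  sil <- vapply(fits, `[[`, numeric(1), "sil")
  best <- which.max(sil)
  f <- fits[[best]]
  structure(list(
    k = k_range[best],
    labels = f$labels,
    medoids = f$medoids,
    silhouette = data.frame(k = k_range, avg_width = sil),
    names = NULL
  ), class = "lt_envclass")
}

#' Name clustered environments WW / LD / MD / ED
#'
#' Computes each cluster's median trajectory. The cluster whose median stays
#' closest to 1 throughout (highest season-mean median stress index) is the
#' well-watered class WW. Remaining clusters are named by the thermal-time
#' centroid of their stressed portion (1 - median): the latest-stressed
#' cluster is LD (late drought), the earliest is ED (early drought), and
#' any in between are MD (mid-season drought). Beyond four clusters,
#' additional ones get generic names. Ties are broken by mean stress.
#'
#' @param classification an `lt_envclass` from [cluster_trajectories()].
#' @param trajectories the matrix that was clustered.
#' @return the classification with `names` (per cluster) and
#'   `season_env` (per season label) filled in.
#' @export
name_environments <- function(classification, trajectories) {
  cl <- classification
  trajectories <- as.matrix(trajectories)
  med <- t(vapply(seq_len(cl$k), function(g) {
    apply(trajectories[cl$labels == g, , drop = FALSE], 2, stats::median)
  }, numeric(100)))
  mean_stress <- rowMeans(med)
  grid <- 1:100
  centroid <- vapply(seq_len(cl$k), function(g) {
    s <- 1 - med[g, ]
    if (sum(s) < 1e-8) return(0) # unstressed: centroid immaterial
    sum(grid * s) / sum(s)
  }, numeric(1))
  nm <- rep(NA_character_, cl$k)
  ww <- order(-mean_stress, centroid)[1]
  nm[ww] <- "WW"
  rest <- setdiff(seq_len(cl$k), ww)
  if (length(rest)) {
    rest <- rest[order(-centroid[rest], mean_stress[rest])] # latest first
    r <- length(rest)
    lbl <- if (r == 1) "LD" else c("LD", rep("MD", r - 2), "ED")
    if (r > 3) {
      # keep one MD (centroid closest to mid-season); extras get generic names
      mids <- rest[2:(r - 1)]
      keep <- which.min(abs(centroid[mids] - 50))
      lbl[2:(r - 1)] <- paste0("C", 4 + seq_len(r - 2))
      lbl[1 + keep] <- "MD"
    }
    nm[rest] <- lbl
  }
  cl$names <- nm
  cl$median_trajectories <- med
  cl$season_env <- nm[cl$labels]
  cl
}

#' Per-site frequency of environment classes
#'
#' @param labels per-season environment labels (e.g. `season_env`).
#' @param site_index per-season site identifier.
#' @return data frame of relative frequencies, one row per site (rows sum
#'   to 1).
#' @export
environment_frequencies <- function(labels, site_index) {
  tab <- table(site = site_index, env = labels)
  freq <- prop.table(tab, 1)
  out <- as.data.frame.matrix(freq)
  out <- cbind(site = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' @export
print.lt_envclass <- function(x, ...) {
  cat(sprintf("<lt_envclass> k = %d (mean silhouette %.3f)\n", x$k,
              x$silhouette$avg_width[x$silhouette$k == x$k]))
  if (!is.null(x$names)) {
    cat("  clusters:", paste(x$names, collapse = ", "), "\n")
    print(table(x$season_env))
  }
  invisible(x)
}
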