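#' Phenotype patients by k-means with gap-statistic model selection
#'
#' Clusters patients on clinical features (severity scores, age, edema
#' indicators, outcome measures — whatever the feature matrix provides) with
#' k-means, choosing the number of clusters by the gap statistic:
#' `Gap(k) = E*[log W_k] - log W_k` against `B` reference data sets drawn
#' uniformly over the observed feature ranges, selecting the smallest `k`
#' with `Gap(k) >= Gap(k+1) - s_{k+1}`. Features are standardized to zero
#' mean and unit variance; patients with any missing feature are dropped
#' (and listed in the result).
#'
#' @param features Data frame or matrix of patient features; rows are
#'   patients (row names or a `patient_id` column identify them).
#' @param k_max Largest number of clusters considered; reduced with a
#'   warning when the patient count is too small.
#' @param B Reference data sets for the gap statistic (default 500).
#' @param n_start Random restarts per k-means run (default 25).
#' @param seed Integer seed making the reference sets reproducible.
#' @return An object of class `nc_phenotype`: list with `k` (chosen),
#'   `assignments` (tibble `patient_id`, `cluster`), `gap_curve` (tibble
#'   `k`, `log_w`, `e_log_w`, `gap`, `se`), `dropped` (patient ids with
#'   incomplete features), `centers`.
#' @export
gap_kmeans <- function(features, k_max = 8, B = 500, n_start = 25, seed = 1) {
  if (is.data.frame(features)) {
    ids <- if ("patient_id" %in% names(features)) {
      as.character(features$patient_id)
    } else {
      rownames(features) %||% as.character(seq_len(nrow(features)))
    }
    x <- as.matrix(features[setdiff(names(features), "patient_id")])
  } else {
    x <- as.matrix(features)
    ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  }
  storage.mode(x) <- "double"
  complete <- stats::complete.cases(x)
  dropped <- ids[!complete]
  if (length(dropped) > 0L) {
    message(length(dropped), " patient(s) dropped for incomplete features")
  }
  x <- x[complete, , drop = FALSE]
  ids <- ids[complete]
  x <- scale(x)
  x <- x[, apply(x, 2, function(col) !anyNA(col)), drop = FALSE] # constant cols
  if (nrow(x) < k_max + 1) {
    k_max <- max(1L, nrow(x) - 1L)
    warning("k_max reduced to ", k_max, " (too few patients)", call. = FALSE)
  }
  km_fun <- function(xx, k) {
    if (k == 1L) {
      list(cluster = rep(1L, nrow(xx)))
    } else {
      stats::kmeans(xx, k, nstart = n_start, iter.max = 50)
    }
  }
  gap <- withr::with_seed(seed, {
    cluster::clusGap(x,
      FUNcluster = km_fun, K.max = k_max, B = B,
      spaceH0 = "original", verbose = FALSE
    )
  })
  tab <- gap$Tab
  k <- cluster::maxSE(tab[, "gap"], tab[, "SE.sim"], method = "Tibs2001SEmax")
  fit <- withr::with_seed(seed + 1L, km_fun(x, k))
  structure(
    list(
      k = as.integer(k),
      assignments = tibble(patient_id = ids, cluster = as.integer(fit$cluster)),
      gap_curve = tibble(
        k = seq_len(k_max), log_w = tab[, "logW"],
        e_log_w = tab[, "E.logW"], gap = tab[, "gap"], se = tab[, "SE.sim"]
      ),
      dropped = dropped,
      centers = if (k > 1L) fit$centers else colMeans(x),
      features = x
    ),
    class = "nc_phenotype"
  )
}

#' @export
print.nc_phenotype <- function(x, ...) {
  cat(
    "k-means phenotyping: k =", x$k, "clusters over",
    nrow(x$assignments), "patients\n"
  )
  print(table(cluster = x$assignments$cluster))
  invisible(x)
}

#' Test whether a relationship concentrates in feature space
#'
#' For each relationship, compares the mean pairwise feature-space distance
#' among the patients exhibiting it against the same statistic for random
#' patient subsets of equal size: a small p-value means those patients sit
#' closer together (a candidate phenotype) than expected from a random
#' distribution. Relationships held by fewer than three patients are
#' skipped.
#'
#' @param features Standardized feature matrix with patient row names (or
#'   the `features` element of a [gap_kmeans()] result).
#' @param relationship_patients Named list: for each relationship, the
#'   character vector of patient ids exhibiting it.
#' @param n_perm Random subsets per relationship (default 1000).
#' @param seed Integer seed.
#' @return Tibble `relationship`, `n_patients`, `observed_distance`,
#'   `p_value` (`NA` when skipped).
#' @export
relationship_cluster_test <- function(features, relationship_patients,
                                      n_perm = 1000, seed = 1) {
  x <- as.matrix(features)
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  d <- as.matrix(stats::dist(x))
  mean_pair_dist <- function(sel) {
    if (length(sel) < 2L) {
      return(NA_real_)
    }
    sub <- d[sel, sel]
    mean(sub[upper.tri(sub)])
  }
  withr::with_seed(seed, {
    purrr::imap_dfr(relationship_patients, function(pats, rel) {
      sel <- which(ids %in% pats)
      if (length(sel) < 3L) {
        return(tibble(
          relationship = rel, n_patients = length(sel),
          observed_distance = NA_real_, p_value = NA_real_
        ))
      }
      obs <- mean_pair_dist(sel)
      null <- vapply(seq_len(n_perm), function(i) {
        mean_pair_dist(sample(length(ids), length(sel)))
      }, numeric(1))
      tibble(
        relationship = rel, n_patients = length(sel),
        observed_distance = obs,
        p_value = (1 + sum(null <= obs)) / (1 + n_perm)
      )
    })
  })
}
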