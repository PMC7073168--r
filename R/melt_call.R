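#' PCA embedding of melt curves
#'
#' Embeds samples in principal-component space by treating each sample's
#' normalized curve as one variable observed over the temperature grid:
#' curves are centred, and the sample coordinates are the entries of the
#' top-k eigenvectors of the sample-by-sample covariance (equivalently, the
#' rotation/loading vectors of a PCA in which curves are the variables).
#' Each component's sign is fixed so that its largest-magnitude entry is
#' positive, making coordinates reproducible across platforms.
#'
#' @param ds_norm A normalized [melt_dataset] with >= 2 samples.
#' @param k Number of components to keep (truncated to the rank of the
#'   data, with a warning).
#' @return An object of class \code{pca_embedding}: \code{coordinates}
#'   (samples x k, rownames = sample ids), \code{explained_fraction}
#'   (length k), \code{explained_full} (all positive eigenvalue fractions,
#'   non-increasing, summing to 1) and \code{k}.
#' @export
pca_embed <- function(ds_norm, k = 3L) {
  stopifnot(inherits(ds_norm, "melt_dataset"))
  x <- ds_norm$fluorescence
  n <- ncol(x)
  if (n < 2L) stop("PCA needs at least 2 samples", call. = FALSE)
  if (max(abs(x - x[, 1])) <= 1e-12 * max(1, max(abs(x))))
    stop("all curves identical: zero variance between samples, nothing ",
         "to embed", call. = FALSE)
  xc <- sweep(x, 2, colMeans(x))          # centre each curve-variable
  sv <- svd(xc, nu = 0)
  if (sv$d[1] <= sqrt(.Machine$double.eps) * sqrt(length(xc)))
    stop("curves carry no variance over the melt region", call. = FALSE)
  rank <- sum(sv$d > sv$d[1] * 1e-8)
  if (k > rank) {
    warning("k = ", k, " exceeds data rank ", rank, "; truncating",
            call. = FALSE)
    k <- rank
  }
  ev <- sv$d^2
  coords <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (coords[which.max(abs(coords[, j])), j] < 0)
      coords[, j] <- -coords[, j]
  }
  rownames(coords) <- ds_norm$sample_ids
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(
    list(coordinates = coords,
         explained_fraction = (ev / sum(ev))[seq_len(k)],
         explained_full = (ev / sum(ev))[seq_len(rank)],
         k = k),
    class = "pca_embedding")
}

#' Choose the number of principal components for clustering
#'
#' Either two or three components are used for clustering; this picks the
#' smallest k in \{2, 3\} whose cumulative explained variance reaches
#' \code{threshold}, defaulting to 3 when neither does (and capping at the
#' number of available components).
#'
#' @param embedding A [pca_embed()] result (its \code{explained_full} is
#'   consulted).
#' @param threshold Cumulative explained-variance target in (0, 1].
#' @return Integer k.
#' @export
choose_k <- function(embedding, threshold = 0.9) {
  stopifnot(threshold > 0, threshold <= 1)
  frac <- embedding$explained_full
  cum <- cumsum(frac)
  avail <- length(frac)
  for (k in 2:3) {
    if (k > avail) return(avail)
    if (cum[k] >= threshold) return(k)
  }
  min(3L, avail)
}

# -- Gaussian mixture machinery ---------------------------------------------

# log density of each row of x under N(mu, sigma); sigma already regularized
mvn_logdens <- function(x, mu, sigma) {
  d <- ncol(x)
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(x) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

# k-means++ seeding: spread initial centres with D^2 sampling
kmeanspp_centers <- function(x, g) {
  n <- nrow(x)
  idx <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[idx, ], "-")^2)
  while (length(idx) < g) {
    nxt <- if (sum(d2) <= 0) sample.int(n, 1) else
      sample.int(n, 1, prob = d2 / sum(d2))
    idx <- c(idx, nxt)
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[nxt, ], "-")^2))
  }
  x[idx, , drop = FALSE]
}

# one EM fit from hard assignments to given centres; errors on failure
em_gmm_once <- function(x, centers, ridge, tol, max_iter) {
  n <- nrow(x); d <- ncol(x); g <- nrow(centers)
  dist2 <- sapply(seq_len(g), function(j)
    rowSums(sweep(x, 2, centers[j, ], "-")^2))
  resp <- matrix(0, n, g)
  resp[cbind(seq_len(n), max.col(-dist2))] <- 1
  ll_old <- -Inf; ll <- -Inf
  for (iter in seq_len(max_iter)) {
    nk <- colSums(resp)
    if (any(nk < sqrt(.Machine$double.eps)))
      stop("empty mixture component", call. = FALSE)
    w <- nk / n
    mu <- crossprod(resp, x) / nk
    logd <- matrix(0, n, g)
    for (j in seq_len(g)) {
      xc <- sweep(x, 2, mu[j, ], "-")
      sigma <- crossprod(xc * resp[, j], xc) / nk[j] + diag(ridge, d)
      logd[, j] <- log(w[j]) + mvn_logdens(x, mu[j, ], sigma)
    }
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    resp <- exp(logd - lse)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      # the diagonal ridge makes the M-step fractionally inexact, so a
      # sub-tolerance dip counts as convergence; a material drop is a bug
      if (ll < ll_old - 1e-6 * max(1, abs(ll_old)))
        stop("EM log-likelihood decreased", call. = FALSE)
      break
    }
    ll_old <- ll
  }
  list(weights = w, means = mu, posterior = resp, loglik = ll,
       n_iter = iter)
}

#' Gaussian-mixture clustering of PC coordinates
#'
#' Fits a G-component Gaussian mixture with full per-component covariances
#' by EM. Covariances carry a small diagonal ridge (1e-6 x trace of the
#' overall covariance / dimension) for numerical stability; initialization
#' is k-means++ with \code{n_restarts} restarts keeping the best
#' log-likelihood; convergence is a log-likelihood gain below \code{tol}.
#' With \code{G = "auto"} the fits for G in \{1, 2, 3\} are compared by BIC.
#' Cluster indices are relabelled in increasing order of the component mean
#' on the first coordinate, so output labels are deterministic given
#' \code{seed}.
#'
#' @param coords Numeric matrix, samples x k (rownames = sample ids), e.g.
#'   from [pca_embed()].
#' @param G Number of genotype groups, or \code{"auto"} for BIC selection.
#' @param seed Integer seed for the restarts.
#' @param n_restarts Number of k-means++ initializations.
#' @param tol,max_iter EM convergence controls.
#' @return An object of class \code{cluster_call_result}: \code{assignments}
#'   (named integer vector), \code{posterior} (samples x G, rows sum to 1),
#'   \code{weights}, \code{means}, \code{loglik}, \code{bic}, \code{G},
#'   plus genotype fields filled in later by [call_variants()].
#' @export
gmm_cluster <- function(coords, G = 3, seed = 1L, n_restarts = 10L,
                        tol = 1e-8, max_iter = 500L) {
  x <- as.matrix(coords)
  storage.mode(x) <- "double"
  n <- nrow(x); d <- ncol(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(n))
  ridge <- 1e-6 * sum(apply(x, 2, stats::var)) / d
  if (ridge <= 0) ridge <- 1e-12
  fit_g <- function(g) {
    if (g == 1L) {
      mu <- matrix(colMeans(x), 1)
      sigma <- crossprod(sweep(x, 2, mu[1, ], "-")) / n + diag(ridge, d)
      ll <- sum(mvn_logdens(x, mu[1, ], sigma))
      return(list(weights = 1, means = mu,
                  posterior = matrix(1, n, 1), loglik = ll, n_iter = 1L))
    }
    if (n <= g) stop("need more samples than mixture components",
                     call. = FALSE)
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- tryCatch(
        em_gmm_once(x, kmeanspp_centers(x, g), ridge, tol, max_iter),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
        best <- fit
    }
    if (is.null(best))
      stop("EM failed on all ", n_restarts, " restarts for G = ", g,
           call. = FALSE)
    best
  }
  set.seed(seed)
  if (identical(G, "auto")) {
    fits <- lapply(1:3, function(g)
      tryCatch(fit_g(g), error = function(e) NULL))
    bics <- vapply(seq_along(fits), function(g) {
      if (is.null(fits[[g]])) return(Inf)
      p <- (g - 1) + g * d + g * d * (d + 1) / 2
      -2 * fits[[g]]$loglik + p * log(n)
    }, numeric(1))
    G <- which.min(bics)
    fit <- fits[[G]]
    bic <- bics[G]
  } else {
    G <- as.integer(G)
    fit <- fit_g(G)
    p <- (G - 1) + G * d + G * d * (d + 1) / 2
    bic <- -2 * fit$loglik + p * log(n)
  }
  ord <- order(fit$means[, 1])
  post <- fit$posterior[, ord, drop = FALSE]
  assign <- max.col(post, ties.method = "first")
  names(assign) <- rownames(x)
  rownames(post) <- rownames(x)
  structure(
    list(assignments = assign, posterior = post,
         weights = fit$weights[ord],
         means = fit$means[ord, , drop = FALSE],
         loglik = fit$loglik, bic = bic, G = G,
         genotype = stats::setNames(rep(NA_character_, n), rownames(x)),
         cluster_genotype = rep(NA_character_, G),
         conflict_flag = rep(FALSE, G),
         seed = seed),
    class = "cluster_call_result")
}

#' Label clusters with anchor genotypes
#'
#' Each cluster inherits the majority genotype among its Sanger-validated
#' anchor samples. Clusters without an anchor stay undetermined
#' (\code{NA}) with a warning; clusters whose anchors disagree get the
#' majority call and a raised \code{conflict_flag}; an exact tie is left
#' undetermined (also flagged).
#'
#' @param result A [gmm_cluster()] result.
#' @param anchors Named character vector mapping anchor sample ids to
#'   known genotypes.
#' @return The result with \code{genotype}, \code{cluster_genotype} and
#'   \code{conflict_flag} filled in.
#' @export
call_variants <- function(result, anchors) {
  stopifnot(inherits(result, "cluster_call_result"))
  if (length(anchors)) {
    missing_ids <- setdiff(names(anchors), names(result$assignments))
    if (length(missing_ids))
      stop("anchor sample(s) not on the plate: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    anchors <- stats::setNames(normalize_genotype(anchors), names(anchors))
  }
  cluster_geno <- rep(NA_character_, result$G)
  conflict <- rep(FALSE, result$G)
  for (g in seq_len(result$G)) {
    members <- names(result$assignments)[result$assignments == g]
    ag <- anchors[intersect(names(anchors), members)]
    if (length(ag) == 0L) {
      warning("cluster ", g, " has no anchor; genotype undetermined",
              call. = FALSE)
      next
    }
    tab <- sort(table(ag), decreasing = TRUE)
    if (length(tab) > 1L) {
      conflict[g] <- TRUE
      if (tab[1] == tab[2]) next         # exact tie: undetermined
    }
    cluster_geno[g] <- names(tab)[1]
  }
  result$cluster_genotype <- cluster_geno
  result$conflict_flag <- conflict
  result$genotype <- stats::setNames(
    cluster_geno[result$assignments], names(result$assignments))
  result
}

#' @export
print.cluster_call_result <- function(x, ...) {
  cat("<cluster_call_result> G =", x$G, " loglik =",
      format(x$loglik, digits = 6), "\n")
  tab <- table(cluster = x$assignments,
               genotype = ifelse(is.na(x$genotype), "undetermined",
                                 x$genotype))
  print(tab)
  invisible(x)
}

#' Genotyping accuracy against Sanger truth
#'
#' The accuracy of a marker is the number of variant calls consistent with
#' Sanger sequencing over the number of Sanger-sequenced samples, as a
#' percentage rounded to one decimal (half away from zero), so 13/14
#' prints as 92.9 and 6/9 as 66.7.
#'
#' @param calls Named character vector of called genotypes (\code{NA} =
#'   undetermined, never counted as consistent).
#' @param sanger Named character vector of Sanger-confirmed genotypes; its
#'   length is the denominator and must be >= 1.
#' @return List with \code{numerator}, \code{denominator}, \code{percent}.
#' @examples
#' genotyping_accuracy(c(a = "A/G", b = "G/G"), c(a = "G/A", b = "A/A"))
#' @export
genotyping_accuracy <- function(calls, sanger) {
  if (length(sanger) < 1L)
    stop("accuracy undefined without Sanger-sequenced samples",
         call. = FALSE)
  sg <- normalize_genotype(sanger)
  cl <- normalize_genotype(calls[names(sanger)])
  num <- sum(!is.na(cl) & cl == sg)
  list(numerator = num, denominator = length(sanger),
       percent = round_half_up(100 * num / length(sanger), 1))
}

#' Run the full HRM-PCA genotype-calling pipeline
#'
#' Composes the calling stages for one marker's plate: clip the curves to
#' the active melt region, normalize, embed with PCA, pick the number of
#' components, cluster with a Gaussian mixture, and label clusters from
#' anchor genotypes. All intermediate artifacts are returned.
#'
#' @param ds A raw [melt_dataset].
#' @param cfg Marker configuration (see [marker_config()]); may be omitted
#'   when \code{lower}/\code{upper} are given directly.
#' @param anchors Named character vector of anchor genotypes (may be
#'   \code{NULL}: clusters are still formed, genotypes stay undetermined).
#' @param lower,upper Optional explicit melt-region limits overriding
#'   \code{cfg}.
#' @param scheme Normalization scheme: \code{"minmax"} (default, the PCA
#'   pipeline's own) or \code{"baseline"} (two-baseline; requires
#'   \code{cfg} with baseline windows).
#' @param G Number of genotype groups or \code{"auto"} (BIC over 1..3).
#' @param k Number of PCs, or \code{"auto"} to use [choose_k()].
#' @param pc_threshold Explained-variance threshold for \code{k = "auto"}.
#' @param seed Integer seed; the whole run is reproducible given it.
#' @return A list of class \code{hrm_call}: \code{clipped},
#'   \code{normalized}, \code{embedding}, \code{k}, \code{result} (a
#'   [gmm_cluster()]/[call_variants()] result), \code{genotype} and
#'   \code{marker_id}.
#' @examples
#' plate <- simulate_plate(simulation_config(n_per_genotype = c(6, 6, 6)))
#' anchors <- plate$truth[c("ref_hom_01", "het_01", "alt_hom_01")]
#' fit <- run_hrm_pca_pipeline(plate$dataset, lower = 74, upper = 82,
#'                             anchors = anchors, seed = 7)
#' genotyping_accuracy(fit$genotype, plate$truth)$percent
#' @export
run_hrm_pca_pipeline <- function(ds, cfg = NULL, anchors = NULL,
                                 lower = NULL, upper = NULL,
                                 scheme = c("minmax", "baseline"),
                                 G = 3, k = "auto", pc_threshold = 0.9,
                                 seed = 1L) {
  scheme <- match.arg(scheme)
  lower <- lower %||% cfg$lower_limit
  upper <- upper %||% cfg$upper_limit
  if (is.null(lower) || is.null(upper))
    stop("melt-region limits required (via cfg or lower/upper)",
         call. = FALSE)
  if (scheme == "baseline") {
    if (is.null(cfg))
      stop("baseline normalization needs a marker configuration",
           call. = FALSE)
    normalized <- clip_melt_region(baseline_normalize(ds, cfg), lower, upper)
    clipped <- clip_melt_region(ds, lower, upper)
  } else {
    clipped <- clip_melt_region(ds, lower, upper)
    normalized <- minmax_normalize(clipped)
  }
  embedding <- pca_embed(normalized, k = 3L)
  k_use <- if (identical(k, "auto")) choose_k(embedding, pc_threshold)
           else min(as.integer(k), embedding$k)
  result <- gmm_cluster(
    embedding$coordinates[, seq_len(k_use), drop = FALSE], G = G,
    seed = seed)
  if (!is.null(anchors)) result <- call_variants(result, anchors)
  structure(
    list(marker_id = ds$marker_id, clipped = clipped,
         normalized = normalized, embedding = embedding, k = k_use,
         result = result, genotype = result$genotype, seed = seed),
    class = "hrm_call")
}

#' @export
print.hrm_call <- function(x, ...) {
  cat("<hrm_call>", if (!is.na(x$marker_id)) x$marker_id else "", "\n  k =",
      x$k, "PCs,", x$result$G, "clusters\n")
  print(x$result)
  invisible(x)
}
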