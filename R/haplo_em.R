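#' Multilocus genotype codes
#'
#' Container for unphased biallelic genotypes coded per locus as 0
#' (homozygous for the reference allele), 1 (heterozygous), 2 (homozygous
#' alternate), with \code{NA} for missing calls.
#'
#' @param codes Integer matrix, individuals x loci, entries in
#'   \{0, 1, 2, NA\}; rownames are sample ids.
#' @param group Optional factor (\code{case} / \code{control}) per
#'   individual; low-CR cultivars map to case, high-CR to control.
#' @param markers Optional locus names.
#' @param ref_alleles,alt_alleles Optional allele letters per locus used to
#'   label haplotypes.
#' @return An object of class \code{multilocus_genotypes}.
#' @export
multilocus_genotypes <- function(codes, group = NULL, markers = NULL,
                                 ref_alleles = NULL, alt_alleles = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (!all(codes %in% c(0L, 1L, 2L, NA)))
    stop("codes must be 0, 1, 2 or NA", call. = FALSE)
  l <- ncol(codes)
  if (l > 6L)
    stop("at most 6 loci supported (haplotype enumeration)", call. = FALSE)
  markers <- markers %||% colnames(codes) %||% paste0("locus", seq_len(l))
  if (is.null(rownames(codes)))
    rownames(codes) <- paste0("ind", seq_len(nrow(codes)))
  colnames(codes) <- markers
  if (!is.null(group)) {
    group <- factor(group, levels = c("case", "control"))
    stopifnot(length(group) == nrow(codes))
  }
  structure(
    list(codes = codes, group = group, markers = markers,
         ref_alleles = ref_alleles %||% rep("A", l),
         alt_alleles = alt_alleles %||% rep("B", l)),
    class = "multilocus_genotypes")
}

#' Encode a genotype table as 0/1/2 multilocus codes
#'
#' Converts diploid genotype strings at the chosen markers into per-locus
#' codes (ref/ref = 0, het = 1, alt/alt = 2, missing propagated) and maps
#' the chilling-requirement classes to a case/control factor (low CR =
#' case, high CR = control).
#'
#' @param gt Long-format genotype table (see [load_genotype_fixture()]).
#' @param markers Character vector of marker ids (the loci, in order).
#' @param ref_alleles Optional reference allele per marker; defaults to
#'   the alphabetically first allele observed at each marker.
#' @return A [multilocus_genotypes] object.
#' @examples
#' gt <- load_genotype_fixture()
#' mg <- encode_genotypes(gt, c("SNP_IGA_122351", "SNP_IGA_134905"))
#' head(mg$codes)
#' @export
encode_genotypes <- function(gt, markers, ref_alleles = NULL) {
  cultivars <- unique(gt$cultivar)
  codes <- matrix(NA_integer_, length(cultivars), length(markers),
                  dimnames = list(cultivars, markers))
  ref <- alt <- character(length(markers))
  for (i in seq_along(markers)) {
    m <- markers[i]
    rows <- gt[gt$marker == m, ]
    if (!nrow(rows)) stop("marker '", m, "' not in the genotype table",
                          call. = FALSE)
    alleles <- sort(unique(unlist(strsplit(rows$genotype[
      !is.na(rows$genotype)], "/"))))
    ref[i] <- ref_alleles[i] %||% alleles[1]
    extra <- setdiff(alleles, ref[i])
    if (length(extra) > 1L) {
      # keep the majority non-ref allele as alt; name a carrier of the rest
      non_ref <- unlist(strsplit(rows$genotype[!is.na(rows$genotype)],
                                 "/"))
      non_ref <- non_ref[non_ref != ref[i]]
      alt_major <- names(which.max(table(non_ref)))
      bad <- rows$cultivar[vapply(rows$genotype, function(g)
        !is.na(g) && any(!strsplit(g, "/")[[1]] %in% c(ref[i],
                                                       alt_major)),
        logical(1))][1]
      stop("marker '", m, "' is not biallelic given ref '", ref[i],
           "' (cultivar '", bad, "')", call. = FALSE)
    }
    alt[i] <- if (length(extra)) extra else ref[i]
    g <- rows$genotype[match(cultivars, rows$cultivar)]
    codes[, i] <- vapply(g, function(s) {
      if (is.na(s)) return(NA_integer_)
      sum(strsplit(s, "/")[[1]] == alt[i]) |> as.integer()
    }, integer(1))
  }
  cls <- gt$cr_class[match(cultivars, gt$cultivar)]
  group <- factor(ifelse(cls == "low", "case", "control"),
                  levels = c("case", "control"))
  multilocus_genotypes(codes, group = group, markers = markers,
                       ref_alleles = ref, alt_alleles = alt)
}

# all 2^L haplotypes as a 0/1 matrix (rows in binary order, locus 1 most
# significant)
hap_bits <- function(l) {
  h <- as.matrix(expand.grid(rep(list(0:1), l))[, l:1, drop = FALSE])
  dimnames(h) <- NULL
  h
}

hap_labels <- function(bits, ref, alt) {
  apply(bits, 1, function(b)
    paste(ifelse(b == 0, ref, alt), collapse = ""))
}

# symmetric H x H compatibility matrix of ordered haplotype pairs for one
# code pattern (NA marginalizes the locus)
pair_compat <- function(pattern, bits) {
  h <- nrow(bits)
  m <- matrix(TRUE, h, h)
  for (l in seq_along(pattern)) {
    c_l <- pattern[l]
    if (is.na(c_l)) next
    a1 <- bits[, l]
    ok <- switch(as.character(c_l),
                 "0" = outer(a1 == 0, a1 == 0, "&"),
                 "1" = outer(a1, a1, "+") == 1,
                 "2" = outer(a1 == 1, a1 == 1, "&"))
    m <- m & ok
  }
  m * 1
}

# one EM run from a given start; asserts the likelihood never decreases;
# the reported log-likelihood is evaluated at the returned frequencies
hap_em_once <- function(f, compat, counts, tol, max_iter) {
  n2 <- 2 * sum(counts)
  loglik_at <- function(f) sum(vapply(seq_along(compat), function(u)
    counts[u] * log(sum(f * (compat[[u]] %*% f))), numeric(1)))
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    exp_counts <- numeric(length(f))
    ll <- 0
    for (u in seq_along(compat)) {
      mf <- compat[[u]] %*% f
      p <- sum(f * mf)
      ll <- ll + counts[u] * log(p)
      exp_counts <- exp_counts + counts[u] * 2 * f * mf[, 1] / p
    }
    if (ll < ll_old - 1e-8)
      stop("EM log-likelihood decreased", call. = FALSE)  # must not happen
    f_new <- exp_counts / n2
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol)
      return(list(f = f, loglik = loglik_at(f), n_iter = iter,
                  converged = TRUE))
    ll_old <- ll
  }
  list(f = f, loglik = loglik_at(f), n_iter = max_iter, converged = FALSE)
}

#' EM haplotype-frequency estimation from unphased genotypes
#'
#' Maximum-likelihood haplotype frequencies under Hardy-Weinberg random
#' union of gametes, by the standard genotype-to-haplotype EM. E-step: each
#' individual's posterior over compatible ordered haplotype pairs is
#' proportional to \code{f_h1 * f_h2} (missing single-locus codes are
#' marginalized, not dropped); M-step: frequencies are expected haplotype
#' counts over 2N. Iteration stops when the largest frequency change falls
#' below \code{tol} or after \code{max_iter} iterations. Runs from a
#' uniform start plus \code{n_starts} random starts, keeping the best
#' log-likelihood; when a run ties the best log-likelihood (within 1e-6)
#' at a visibly different frequency vector, the solution is flagged as
#' non-identifiable (a flat likelihood ridge, e.g. a sample of pure double
#' heterozygotes).
#'
#' @param data A [multilocus_genotypes] object, or a plain 0/1/2 code
#'   matrix (individuals x loci).
#' @param tol Convergence tolerance on max |delta f|.
#' @param max_iter Iteration cap.
#' @param seed Seed for the random restarts.
#' @param n_starts Number of random restarts added to the uniform start.
#' @return An object of class \code{haplotype_estimate}:
#'   \code{haplotypes} (allele strings, lexicographic), \code{frequencies}
#'   (named, summing to 1), \code{loglik}, \code{n_iter},
#'   \code{converged}, \code{identifiable}, \code{n}.
#' @examples
#' mg <- encode_genotypes(load_genotype_fixture(),
#'                        c("SNP_IGA_122351", "SNP_IGA_134905"))
#' em_haplotype_frequencies(mg)
#' @export
em_haplotype_frequencies <- function(data, tol = 1e-8, max_iter = 10000L,
                                     seed = 1L, n_starts = 5L) {
  if (!inherits(data, "multilocus_genotypes"))
    data <- multilocus_genotypes(data)
  codes <- data$codes
  if (!nrow(codes)) stop("no individuals", call. = FALSE)
  if (!any(stats::complete.cases(codes)))
    stop("no individual has complete codes at all loci", call. = FALSE)
  l <- ncol(codes)
  bits <- hap_bits(l)
  labels <- hap_labels(bits, data$ref_alleles, data$alt_alleles)
  pat_key <- apply(codes, 1, paste, collapse = ",")
  uniq <- !duplicated(pat_key)
  compat <- lapply(which(uniq), function(i) pair_compat(codes[i, ], bits))
  counts <- as.numeric(table(factor(pat_key, levels = pat_key[uniq])))
  h <- nrow(bits)
  set.seed(seed)
  starts <- c(list(rep(1 / h, h)),
              lapply(seq_len(n_starts), function(s) {
                g <- stats::rgamma(h, 1)
                g / sum(g)
              }))
  runs <- lapply(starts, hap_em_once, compat = compat, counts = counts,
                 tol = tol, max_iter = max_iter)
  lls <- vapply(runs, `[[`, numeric(1), "loglik")
  best <- runs[[which.max(lls)]]
  identifiable <- TRUE
  for (r in runs) {
    if (abs(r$loglik - best$loglik) < 1e-6 &&
        max(abs(r$f - best$f)) > 1e-4) identifiable <- FALSE
  }
  if (!best$converged)
    warning("haplotype EM did not converge in ", max_iter, " iterations",
            call. = FALSE)
  ord <- order(labels, method = "radix")
  structure(
    list(haplotypes = labels[ord],
         frequencies = stats::setNames(best$f[ord], labels[ord]),
         loglik = best$loglik, n_iter = best$n_iter,
         converged = best$converged, identifiable = identifiable,
         n = nrow(codes), markers = data$markers),
    class = "haplotype_estimate")
}

#' @export
print.haplotype_estimate <- function(x, digits = 4, ...) {
  cat("<haplotype_estimate> ", paste(x$markers, collapse = "-"), ": n = ",
      x$n, ", loglik = ", format(x$loglik, digits = 6),
      if (!x$identifiable) " (non-identifiable ridge)", "\n", sep = "")
  print(round(x$frequencies, digits))
  invisible(x)
}

#' Case/control-stratified haplotype frequencies
#'
#' Runs [em_haplotype_frequencies()] on the pooled data and on the case
#' (low CR) and control (high CR) subsets, reporting all three frequency
#' vectors over the same haplotype set.
#'
#' @inheritParams em_haplotype_frequencies
#' @return An object of class \code{case_control_haplotypes}:
#'   \code{haplotypes}, \code{freq_overall}, \code{freq_case},
#'   \code{freq_control}, and the three underlying \code{fits}.
#' @export
case_control_haplotype_freqs <- function(data, tol = 1e-8,
                                         max_iter = 10000L, seed = 1L,
                                         n_starts = 5L) {
  stopifnot(inherits(data, "multilocus_genotypes"))
  if (is.null(data$group) || anyNA(data$group))
    stop("case/control analysis needs a complete group factor",
         call. = FALSE)
  subsets <- list(overall = rep(TRUE, nrow(data$codes)),
                  case = data$group == "case",
                  control = data$group == "control")
  if (!all(vapply(subsets, any, logical(1))))
    stop("both case and control groups must be non-empty", call. = FALSE)
  fits <- lapply(subsets, function(keep) {
    sub <- multilocus_genotypes(data$codes[keep, , drop = FALSE],
                                markers = data$markers,
                                ref_alleles = data$ref_alleles,
                                alt_alleles = data$alt_alleles)
    em_haplotype_frequencies(sub, tol = tol, max_iter = max_iter,
                             seed = seed, n_starts = n_starts)
  })
  structure(
    list(haplotypes = fits$overall$haplotypes,
         freq_overall = fits$overall$frequencies,
         freq_case = fits$case$frequencies,
         freq_control = fits$control$frequencies,
         fits = fits, markers = data$markers),
    class = "case_control_haplotypes")
}

#' @export
print.case_control_haplotypes <- function(x, digits = 4, ...) {
  cat("<case_control_haplotypes> ", paste(x$markers, collapse = "-"),
      "\n", sep = "")
  print(round(cbind(overall = x$freq_overall, case = x$freq_case,
                    control = x$freq_control), digits))
  invisible(x)
}

#' Simulate unphased genotypes under Hardy-Weinberg equilibrium
#'
#' Draws two haplotypes per individual i.i.d. from the given frequency
#' vector and collapses them to 0/1/2 codes; the test harness for the EM
#' estimator.
#'
#' @param haplotype_freqs Named numeric vector summing to 1; names are
#'   equal-length allele strings (at most two alleles per position). An
#'   unnamed vector of length 2^L is labelled with A (ref) / B (alt) in
#'   binary order.
#' @param n Number of individuals (>= 1).
#' @param seed Integer seed.
#' @param group Optional group label recycled over individuals.
#' @return A [multilocus_genotypes] object.
#' @export
simulate_hwe_genotypes <- function(haplotype_freqs, n, seed = 1L,
                                   group = NULL) {
  f <- haplotype_freqs
  if (any(f < 0) || abs(sum(f) - 1) > 1e-8)
    stop("haplotype frequencies must be non-negative and sum to 1",
         call. = FALSE)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (is.null(names(f))) {
    l <- round(log2(length(f)))
    if (2^l != length(f))
      stop("unnamed frequency vector must have length 2^L", call. = FALSE)
    bits <- hap_bits(l)
    ref <- rep("A", l); alt <- rep("B", l)
  } else {
    chars <- strsplit(names(f), "")
    l <- unique(lengths(chars))
    if (length(l) != 1L)
      stop("haplotype names must share one length", call. = FALSE)
    ref <- alt <- character(l)
    bits <- matrix(0L, length(f), l)
    for (j in seq_len(l)) {
      al <- sort(unique(vapply(chars, `[[`, character(1), j)))
      if (length(al) > 2L)
        stop("more than two alleles at position ", j, call. = FALSE)
      ref[j] <- al[1]; alt[j] <- al[length(al)]
      bits[, j] <- as.integer(vapply(chars, `[[`, character(1), j) ==
                                alt[j] & length(al) > 1L)
    }
  }
  set.seed(seed)
  i1 <- sample.int(length(f), n, replace = TRUE, prob = f)
  i2 <- sample.int(length(f), n, replace = TRUE, prob = f)
  codes <- bits[i1, , drop = FALSE] + bits[i2, , drop = FALSE]
  multilocus_genotypes(codes, group = if (!is.null(group))
    rep(group, length.out = n), ref_alleles = ref, alt_alleles = alt)
}
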