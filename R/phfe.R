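#' Probabilistic hesitant fuzzy elements
#'
#' A probabilistic hesitant fuzzy element (PHFE) records the membership
#' degrees a group of decision makers hesitates between, together with the
#' probability (preference weight) attached to each degree. It is written
#' \{gamma_1|p_1, ..., gamma_l|p_l\} with all gamma_i and p_i in [0, 1] and
#' the p_i summing to 1. Zero-probability entries are permitted: they arise
#' naturally from pessimistic length padding (see [pad_pessimistic()]).
#'
#' @param membership numeric vector of membership degrees in [0, 1].
#' @param probability numeric vector of probabilities in [0, 1] summing to 1;
#'   defaults to equal probabilities \code{1/l}.
#' @return An object of class \code{"phfe"}: a list with components
#'   \code{m} (membership) and \code{p} (probability).
#' @examples
#' h1 <- phfe(c(0.2, 0.8), c(0.6, 0.4))
#' phf_score(h1)      # 0.44
#' phf_deviation(h1)  # 0.0864
#' @seealso [phfs()], [phf_score()], [phf_deviation()], [canonical_sort()]
#' @export
phfe <- function(membership, probability = NULL) {
  m <- as.numeric(membership)
  if (is.null(probability)) probability <- rep(1 / length(m), length(m))
  p <- as.numeric(probability)
  validate_phfe(structure(list(m = m, p = p), class = "phfe"))
}

#' Validate a probabilistic hesitant fuzzy element
#'
#' Checks the PHFE invariants: memberships in [0, 1], probabilities in
#' [0, 1], and probabilities summing to 1 within a tolerance of 1e-9.
#' Each violation signals a distinct condition class so callers can react
#' programmatically: \code{"phf_membership_error"},
#' \code{"phf_probability_error"} and \code{"phf_prob_sum_error"}, all
#' inheriting from \code{"phf_validation_error"}.
#'
#' @param h object of class \code{"phfe"}.
#' @param tol tolerance on the probability sum (default 1e-9).
#' @return \code{h}, unchanged, if all invariants hold.
#' @export
validate_phfe <- function(h, tol = 1e-9) {
  if (!inherits(h, "phfe")) {
    h <- structure(list(m = as.numeric(h$m), p = as.numeric(h$p)), class = "phfe")
  }
  m <- h$m; p <- h$p
  if (length(m) == 0L || length(m) != length(p)) {
    stop(phf_error("a PHFE needs matching, non-empty membership and probability vectors",
                   "phf_membership_error"))
  }
  if (anyNA(m) || any(m < 0) || any(m > 1)) {
    stop(phf_error("PHFE memberships must lie in [0, 1]", "phf_membership_error"))
  }
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop(phf_error("PHFE probabilities must lie in [0, 1]", "phf_probability_error"))
  }
  if (abs(sum(p) - 1) > tol) {
    stop(phf_error(sprintf("PHFE probabilities must sum to 1 (got %.10g)", sum(p)),
                   "phf_prob_sum_error"))
  }
  h
}

phf_error <- function(msg, class) {
  errorCondition(msg, class = c(class, "phf_validation_error", "phf_error"))
}

#' @export
print.phfe <- function(x, digits = 4, ...) {
  cat("{", paste0(format(x$m, digits = digits), "|",
                  format(x$p, digits = digits), collapse = ", "), "}\n")
  invisible(x)
}

#' @export
length.phfe <- function(x) length(x$m)

#' Probabilistic hesitant fuzzy sets
#'
#' A PHFS assigns one PHFE to every item of a finite universe (for
#' decision problems: one evaluation per criterion).
#'
#' @param ... PHFE objects, or a single list of PHFE objects.
#' @return An object of class \code{"phfs"}: a list of \code{"phfe"}.
#' @examples
#' A <- phfs(phfe(c(0.5, 0.8, 0.7), c(0.4, 0.3, 0.3)),
#'           phfe(c(0.1, 0.3, 0.6), c(0.5, 0.3, 0.2)),
#'           phfe(c(0.2, 0.3), c(0.7, 0.3)))
#' information_energy(A)  # 0.0694
#' @export
phfs <- function(...) {
  el <- list(...)
  if (length(el) == 1L && is.list(el[[1]]) && !inherits(el[[1]], "phfe")) {
    el <- el[[1]]
  }
  if (length(el) < 1L) stop(phf_error("a PHFS needs at least one element", "phf_membership_error"))
  el <- lapply(el, validate_phfe)
  structure(el, class = "phfs")
}

#' @export
print.phfs <- function(x, ...) {
  cat("PHFS over", length(x), "items\n")
  for (i in seq_along(x)) { cat(sprintf("  x%d: ", i)); print(x[[i]], ...) }
  invisible(x)
}

#' @export
`[.phfs` <- function(x, i) structure(unclass(x)[i], class = "phfs")

#' Hesitant fuzzy elements (no probabilities)
#'
#' The plain hesitant fuzzy element keeps only the candidate membership
#' values; it is used by the baseline hesitant-fuzzy correlation
#' coefficient (see [hfs_rho()]).
#'
#' @param values numeric vector of membership values in [0, 1].
#' @return An object of class \code{"hfe"}.
#' @export
hfe <- function(values) {
  v <- as.numeric(values)
  if (length(v) == 0L) stop(phf_error("an HFE must be non-empty", "phf_membership_error"))
  if (anyNA(v) || any(v < 0) || any(v > 1)) {
    stop(phf_error("HFE values must lie in [0, 1]", "phf_membership_error"))
  }
  structure(list(v = v), class = "hfe")
}

#' Score of a PHFE
#'
#' The score is the probability-weighted mean membership,
#' \eqn{s(h) = \sum_i \gamma_i p_i}. It is the primary key when comparing
#' PHFEs: a higher score is better.
#'
#' @param h a \code{"phfe"}.
#' @return A number in [0, 1].
#' @examples phf_score(phfe(c(0.2, 0.8), c(0.6, 0.4)))  # 0.44
#' @export
phf_score <- function(h) sum(h$m * h$p)

#' Deviation of a PHFE
#'
#' The deviation is the probability-weighted squared dispersion about the
#' score, \eqn{\delta(h) = \sum_i (\gamma_i - s(h))^2 p_i}. It is the
#' tie-break key when two PHFEs have equal score: the lower deviation (the
#' less hesitant evaluation) wins.
#'
#' @param h a \code{"phfe"}.
#' @return A non-negative number.
#' @export
phf_deviation <- function(h) {
  s <- sum(h$m * h$p)
  sum((h$m - s)^2 * h$p)
}

#' Compare two PHFEs
#'
#' Comparison is by score, then (on equal score) by deviation with the
#' smaller deviation ranked higher; equal score and deviation compare as
#' equal.
#'
#' @param a,b \code{"phfe"} objects.
#' @return -1, 0 or 1 if \code{a} is worse than, equivalent to, or better
#'   than \code{b}.
#' @examples
#' phf_compare(phfe(c(0.2, 0.8), c(0.6, 0.4)),
#'             phfe(c(0.6, 0.4), c(0.2, 0.8)))  # -1: equal score, higher deviation
#' @export
phf_compare <- function(a, b) {
  sa <- phf_score(a); sb <- phf_score(b)
  if (sa > sb) return(1L)
  if (sa < sb) return(-1L)
  da <- phf_deviation(a); db <- phf_deviation(b)
  if (da < db) return(1L)
  if (da > db) return(-1L)
  0L
}

#' Canonical (F-ascending) ordering of a PHFE
#'
#' Entries are permuted so that \eqn{F_j = \gamma_j p_j} is non-decreasing;
#' ties are broken by membership then probability, ascending, with a stable
#' sort. This canonical order is what makes pairwise alignment of two
#' PHFEs well defined.
#'
#' @param h a \code{"phfe"}.
#' @return The same element with entries in canonical order.
#' @examples
#' canonical_sort(phfe(c(0.2, 0.3), c(0.7, 0.3)))  # (0.3|0.3, 0.2|0.7)
#' @export
canonical_sort <- function(h) {
  o <- order(h$m * h$p, h$m, h$p, method = "radix")
  structure(list(m = h$m[o], p = h$p[o]), class = "phfe")
}

#' Pessimistic padding of a canonical PHFE
#'
#' Extends a canonically sorted PHFE to \code{target_len} entries by
#' prepending copies of the worst entry's membership (the membership of the
#' minimum-F entry) at probability 0. The padded entries have F = 0, so the
#' result stays in canonical order, and the probability sum and score are
#' unchanged. Note that the padded membership is the minimum-F entry's
#' membership, which need not be the minimum membership value.
#'
#' @param h a canonically sorted \code{"phfe"} (see [canonical_sort()]).
#' @param target_len desired length, at least \code{length(h)}.
#' @param padding \code{"pessimistic"} (default) prepends the minimum-F
#'   membership; \code{"optimistic"} appends the maximum-F membership
#'   (probability 0 either way).
#' @return A \code{"phfe"} of length \code{target_len}.
#' @export
pad_pessimistic <- function(h, target_len, padding = c("pessimistic", "optimistic")) {
  padding <- match.arg(padding)
  l <- length(h$m)
  if (target_len < l) {
    stop(phf_error("target_len is smaller than the element length", "phf_error"))
  }
  if (target_len == l) return(h)
  k <- target_len - l
  if (padding == "pessimistic") {
    structure(list(m = c(rep(h$m[1L], k), h$m), p = c(rep(0, k), h$p)), class = "phfe")
  } else {
    structure(list(m = c(h$m, rep(h$m[l], k)), p = c(h$p, rep(0, k))), class = "phfe")
  }
}

#' Align two PHFEs for pairwise computation
#'
#' Both elements are put in canonical F-ascending order and the shorter one
#' is padded (pessimistically by default) to the common length
#' \eqn{l = \max(l_a, l_b)}.
#'
#' @param a,b \code{"phfe"} objects.
#' @param padding passed to [pad_pessimistic()].
#' @return A list with components \code{a}, \code{b} (aligned elements) and
#'   \code{l} (the common length).
#' @export
phf_align <- function(a, b, padding = "pessimistic") {
  a <- canonical_sort(a); b <- canonical_sort(b)
  l <- max(length(a$m), length(b$m))
  list(a = pad_pessimistic(a, l, padding), b = pad_pessimistic(b, l, padding), l = l)
}
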