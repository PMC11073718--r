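#' Information energy of a PHFS
#'
#' The information energy plays the role of a self-inner-product for a
#' PHFS: \eqn{\psi(A) = \sum_i (1/l_i) \sum_j (\gamma_{ij} p_{ij})^2},
#' where \eqn{l_i} is the number of entries of the i-th element (its own,
#' unpadded length).
#'
#' @param A a \code{"phfs"}.
#' @return A non-negative number.
#' @examples
#' A <- phfs(phfe(c(0.5, 0.8, 0.7), c(0.4, 0.3, 0.3)),
#'           phfe(c(0.1, 0.3, 0.6), c(0.5, 0.3, 0.2)),
#'           phfe(c(0.2, 0.3), c(0.7, 0.3)))
#' information_energy(A)  # 0.0694
#' @export
information_energy <- function(A) {
  sum(vapply(A, function(h) mean((h$m * h$p)^2), numeric(1)))
}

# Per-item statistics for a pair of PHFSs under the standard alignment:
# cross_i = (1/l_i^max) sum_j gamma_a gamma_b p_a p_b with both elements
# F-sorted and the shorter padded at probability 0; ea_i/eb_i are the
# own-length (unpadded) per-item energies. Everything downstream (rho1-4)
# is a weighted combination of these three vectors.
pair_item_stats <- function(A, B, padding = "pessimistic") {
  n <- length(A)
  if (length(B) != n) {
    stop(phf_error("PHFSs must be defined over the same universe", "phf_universe_error"))
  }
  cross <- ea <- eb <- numeric(n)
  for (i in seq_len(n)) {
    ha <- A[[i]]; hb <- B[[i]]
    ea[i] <- mean((ha$m * ha$p)^2)
    eb[i] <- mean((hb$m * hb$p)^2)
    al <- phf_align(ha, hb, padding)
    # multiply the per-entry F = gamma*p products so the cross term is
    # exactly symmetric in A and B
    cross[i] <- sum((al$a$m * al$a$p) * (al$b$m * al$b$p)) / al$l
  }
  list(cross = cross, ea = ea, eb = eb, n = n)
}

#' Correlation between two PHFSs
#'
#' The information-energy cross term: per universe item the two elements
#' are aligned (canonical sort plus pessimistic padding to the larger
#' length \eqn{l_i}), then \eqn{(1/l_i)\sum_j \gamma_A \gamma_B p_A p_B}
#' is accumulated over items. Symmetric, and
#' \code{correlation_c1(A, A) == information_energy(A)}.
#'
#' @param A,B \code{"phfs"} objects over the same universe.
#' @param padding alignment flag, see [pad_pessimistic()].
#' @return A non-negative number.
#' @export
correlation_c1 <- function(A, B, padding = "pessimistic") {
  sum(pair_item_stats(A, B, padding)$cross)
}

check_energy <- function(e, who) {
  if (e <= 0) {
    stop(phf_error(sprintf("information energy of %s is zero; the correlation coefficient is undefined", who),
                   "phf_zero_energy_error"))
  }
  e
}

#' Information-energy correlation coefficients for PHFSs
#'
#' The four coefficients normalize the cross term [correlation_c1()] by the
#' two sets' information energies. \code{rho1} uses the geometric mean of
#' the energies (a Cauchy-Schwarz normalization), \code{rho2} the maximum
#' of the energies; \code{rho3} and \code{rho4} are the weighted analogues
#' in which every per-item term (cross and both energies) is multiplied by
#' the item weight before summation. All four lie in [0, 1], equal 1 when
#' the sets coincide, and satisfy \code{rho2 <= rho1} and
#' \code{rho4 <= rho3}. With uniform weights \code{rho3} and \code{rho4}
#' reduce exactly to \code{rho1} and \code{rho2}.
#'
#' A key convention, fixed by the defining formulas: the cross term divides
#' by the aligned (maximum) length per item, while the energies in the
#' denominators always use each set's own unpadded lengths.
#'
#' @param A,B \code{"phfs"} objects over the same universe.
#' @param w item weight vector for \code{rho3}/\code{rho4}: non-negative,
#'   summing to 1, one weight per universe item.
#' @param padding alignment flag, see [pad_pessimistic()].
#' @return A number in [0, 1]. Zero information energy in either set
#'   signals a \code{"phf_zero_energy_error"} rather than returning NaN.
#' @examples
#' A <- phfs(phfe(c(0.5, 0.8, 0.7), c(0.4, 0.3, 0.3)),
#'           phfe(c(0.1, 0.3, 0.6), c(0.5, 0.3, 0.2)),
#'           phfe(c(0.2, 0.3), c(0.7, 0.3)))
#' B <- phfs(phfe(c(0.4, 0.5), c(0.3, 0.7)),
#'           phfe(c(0.2, 0.3, 0.5), c(0.4, 0.1, 0.5)),
#'           phfe(c(0.3, 0.8, 0.7), c(0.2, 0.1, 0.7)))
#' rho1(A, B)  # 0.6764
#' @export
rho1 <- function(A, B, padding = "pessimistic") {
  st <- pair_item_stats(A, B, padding)
  sum(st$cross) / sqrt(check_energy(sum(st$ea), "A") * check_energy(sum(st$eb), "B"))
}

#' @rdname rho1
#' @export
rho2 <- function(A, B, padding = "pessimistic") {
  st <- pair_item_stats(A, B, padding)
  sum(st$cross) / check_energy(max(sum(st$ea), sum(st$eb)), "A and B")
}

#' @rdname rho1
#' @export
rho3 <- function(A, B, w, padding = "pessimistic") {
  w <- validate_weights(w, length(A))
  st <- pair_item_stats(A, B, padding)
  sum(w * st$cross) /
    sqrt(check_energy(sum(w * st$ea), "A") * check_energy(sum(w * st$eb), "B"))
}

#' @rdname rho1
#' @export
rho4 <- function(A, B, w, padding = "pessimistic") {
  w <- validate_weights(w, length(A))
  st <- pair_item_stats(A, B, padding)
  sum(w * st$cross) / check_energy(max(sum(w * st$ea), sum(w * st$eb)), "A and B")
}

#' Validate a weight vector
#'
#' @param w numeric vector of non-negative weights summing to 1.
#' @param n required length (universe size); NULL skips the length check.
#' @param tol tolerance on the sum.
#' @return \code{w} as a plain numeric vector.
#' @export
validate_weights <- function(w, n = NULL, tol = 1e-9) {
  w <- as.numeric(w)
  if (!is.null(n) && length(w) != n) {
    stop(phf_error(sprintf("expected %d weights, got %d", n, length(w)), "phf_weight_error"))
  }
  if (anyNA(w) || any(w < 0)) {
    stop(phf_error("weights must be non-negative", "phf_weight_error"))
  }
  if (abs(sum(w) - 1) > tol) {
    stop(phf_error(sprintf("weights must sum to 1 (got %.10g)", sum(w)), "phf_weight_error"))
  }
  w
}

#' Full correlation report for a pair of PHFSs
#'
#' Computes the two information energies, the cross term and the requested
#' coefficient in one pass; useful for auditing a coefficient value.
#'
#' @param A,B \code{"phfs"} objects over the same universe.
#' @param method one of \code{"rho1"}, \code{"rho2"}, \code{"rho3"},
#'   \code{"rho4"}, \code{"song"}, \code{"song-w"}.
#' @param w weights (required for \code{rho3}, \code{rho4}, \code{song-w}).
#' @param padding alignment flag.
#' @return A list of class \code{"phf_correlation"} with components
#'   \code{energy_a}, \code{energy_b}, \code{cross}, \code{coefficient},
#'   \code{method}.
#' @export
phf_correlation <- function(A, B,
                            method = c("rho1", "rho2", "rho3", "rho4", "song", "song-w"),
                            w = NULL, padding = "pessimistic") {
  method <- match.arg(method)
  if (method %in% c("rho3", "rho4", "song-w") && is.null(w)) {
    stop(phf_error(sprintf("method '%s' needs a weight vector", method), "phf_weight_error"))
  }
  coef <- switch(method,
    "rho1"   = rho1(A, B, padding),
    "rho2"   = rho2(A, B, padding),
    "rho3"   = rho3(A, B, w, padding),
    "rho4"   = rho4(A, B, w, padding),
    "song"   = song_rho(A, B),
    "song-w" = song_rho_weighted(A, B, w))
  structure(list(energy_a = information_energy(A), energy_b = information_energy(B),
                 cross = correlation_c1(A, B, padding),
                 coefficient = coef, method = method),
            class = "phf_correlation")
}

#' @export
print.phf_correlation <- function(x, ...) {
  cat(sprintf("PHFS correlation (%s): %.4f\n", x$method, x$coefficient))
  cat(sprintf("  energy A: %.4f  energy B: %.4f  cross: %.4f\n",
              x$energy_a, x$energy_b, x$cross))
  invisible(x)
}

#' Mean/variance baseline correlation (Song et al.)
#'
#' The baseline coefficient reduces each element to its mean
#' \eqn{\sum_j \gamma_j p_j} and computes a Pearson-style coefficient of
#' the two per-element mean vectors. It illustrates a known degeneracy:
#' whenever the corresponding element means of two different PHFSs agree,
#' the coefficient is 1 even though the sets differ — the
#' information-energy coefficients [rho1()] distinguish such sets.
#'
#' @param A,B \code{"phfs"} objects over the same universe (n >= 2).
#' @param w optional item weights for the weighted form.
#' @return A number in [-1, 1]. Zero variance of either mean vector signals
#'   a \code{"phf_zero_energy_error"}.
#' @export
song_rho <- function(A, B) {
  n <- length(A)
  if (length(B) != n) stop(phf_error("PHFSs must share a universe", "phf_universe_error"))
  if (n < 2L) stop(phf_error("the mean/variance baseline needs n >= 2", "phf_universe_error"))
  ma <- vapply(A, phf_score, numeric(1))
  mb <- vapply(B, phf_score, numeric(1))
  song_normalized(ma, mb)
}

#' @rdname song_rho
#' @export
song_rho_weighted <- function(A, B, w) {
  n <- length(A)
  if (length(B) != n) stop(phf_error("PHFSs must share a universe", "phf_universe_error"))
  w <- validate_weights(w, n)
  ma <- w * vapply(A, phf_score, numeric(1))
  mb <- w * vapply(B, phf_score, numeric(1))
  song_normalized(ma, mb)
}

song_normalized <- function(ma, mb) {
  ca <- mean((ma - mean(ma))^2)
  cb <- mean((mb - mean(mb))^2)
  check_energy(ca, "A"); check_energy(cb, "B")
  mean((ma - mean(ma)) * (mb - mean(mb))) / sqrt(ca * cb)
}

#' Hesitant-fuzzy baseline correlation coefficient (Chen et al.)
#'
#' The plain hesitant-fuzzy analogue of [rho1()], ignoring probabilities.
#' Element values are sorted ascending and the shorter element is padded by
#' repeating its minimum value (pessimistic criterion); the cross term uses
#' the aligned length per item and the self-correlations use each set's own
#' lengths. A weighted variant multiplies every per-item term by the item
#' weight.
#'
#' @param A,B lists of \code{"hfe"} objects (or plain numeric vectors) over
#'   the same universe.
#' @param w optional item weights; NULL (the default) gives the unweighted
#'   coefficient.
#' @return A number in [0, 1].
#' @export
hfs_rho <- function(A, B, w = NULL) {
  A <- lapply(A, as_hfe_values); B <- lapply(B, as_hfe_values)
  n <- length(A)
  if (length(B) != n) stop(phf_error("HFSs must share a universe", "phf_universe_error"))
  w <- if (is.null(w)) rep(1, n) else validate_weights(w, n) * n
  cross <- ea <- eb <- numeric(n)
  for (i in seq_len(n)) {
    va <- sort(A[[i]]); vb <- sort(B[[i]])
    ea[i] <- mean(va^2); eb[i] <- mean(vb^2)
    l <- max(length(va), length(vb))
    va <- c(rep(va[1L], l - length(va)), va)
    vb <- c(rep(vb[1L], l - length(vb)), vb)
    cross[i] <- sum(va * vb) / l
  }
  sum(w * cross) /
    sqrt(check_energy(sum(w * ea), "A") * check_energy(sum(w * eb), "B"))
}

as_hfe_values <- function(x) {
  if (inherits(x, "hfe")) x$v else hfe(x)$v
}
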