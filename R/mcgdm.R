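#' Saaty 1-9 value of a linguistic term
#'
#' Maps the nine-term linguistic vocabulary used by the decision makers
#' (Very low ... Very high) onto Saaty's 1-9 scale:
#' VL=1, VLL=2, L=3, ML=4, M=5, MH=6, H=7, HVH=8, VH=9.
#'
#' @param term character vector of term labels.
#' @return An integer vector of scale values.
#' @examples saaty_value(c("VH", "VL"))  # 9 1
#' @export
saaty_value <- function(term) {
  scale <- c(VL = 1L, VLL = 2L, L = 3L, ML = 4L, M = 5L,
             MH = 6L, H = 7L, HVH = 8L, VH = 9L)
  v <- scale[as.character(term)]
  if (anyNA(v)) {
    bad <- unique(as.character(term)[is.na(v)])
    stop(phf_error(sprintf("unknown linguistic term(s): %s", paste(bad, collapse = ", ")),
                   "phf_term_error"))
  }
  unname(v)
}

round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  floor(x * s + 0.5 + 1e-9) / s
}

#' Group decision problem
#'
#' Bundles the ingredients of a multi-criteria group decision problem:
#' alternatives, criteria with their benefit/cost direction, experts with
#' weights, and either (a) per-expert linguistic evaluation matrices (rows
#' = criteria, columns = alternatives) plus an experts-by-criteria
#' importance grid or an explicit criteria weight vector, or (b) a ready
#' probabilistic hesitant fuzzy decision matrix (see [phf_matrix()]), in
#' which case only the ideal-construction and ranking steps apply.
#'
#' @param alternatives character vector of alternative names.
#' @param criteria character vector of criterion names.
#' @param directions character vector, one of \code{"benefit"}/\code{"cost"}
#'   per criterion.
#' @param linguistic named list (one per expert) of criteria x alternatives
#'   character matrices of linguistic terms.
#' @param expert_weights numeric vector of expert weights (default equal).
#' @param importance experts x criteria character matrix of linguistic
#'   importance judgements (used to derive criteria weights).
#' @param weights explicit criteria weights; overrides \code{importance}.
#' @param phf_matrix a \code{"phf_matrix"} supplying the decision matrix
#'   directly, bypassing the linguistic steps.
#' @return An object of class \code{"phf_problem"}.
#' @seealso [phf_evaluate()]
#' @export
phf_problem <- function(alternatives, criteria, directions,
                        linguistic = NULL, expert_weights = NULL,
                        importance = NULL, weights = NULL, phf_matrix = NULL) {
  directions <- match.arg(directions, c("benefit", "cost"), several.ok = TRUE)
  if (length(directions) != length(criteria)) {
    stop(phf_error("one direction per criterion is required", "phf_problem_error"))
  }
  if (is.null(linguistic) && is.null(phf_matrix)) {
    stop(phf_error("either linguistic matrices or a PHF decision matrix is required",
                   "phf_problem_error"))
  }
  if (!is.null(linguistic)) {
    k <- length(linguistic)
    if (is.null(expert_weights)) expert_weights <- rep(1 / k, k)
    expert_weights <- validate_weights(expert_weights, k)
    for (g in linguistic) {
      if (!is.matrix(g) || nrow(g) != length(criteria) || ncol(g) != length(alternatives)) {
        stop(phf_error("each linguistic matrix must be criteria x alternatives",
                       "phf_problem_error"))
      }
      if (anyNA(g) || any(!nzchar(g))) {
        stop(phf_error("linguistic matrices must have no missing cells", "phf_problem_error"))
      }
      saaty_value(g)  # vocabulary check
    }
  }
  if (!is.null(weights)) weights <- validate_weights(weights, length(criteria))
  structure(list(alternatives = alternatives, criteria = criteria,
                 directions = directions, linguistic = linguistic,
                 expert_weights = expert_weights, importance = importance,
                 weights = weights, phf_matrix = phf_matrix),
            class = "phf_problem")
}

#' Criteria weights from linguistic importance judgements
#'
#' Each expert rates every criterion on the linguistic scale; ratings are
#' converted to Saaty values, combined with the expert weights into an
#' integrated weight per criterion, and normalized to sum to 1.
#'
#' @param importance experts x criteria character matrix of linguistic terms.
#' @param expert_weights numeric vector of expert weights (default equal).
#' @return A numeric weight vector summing to 1, with the pre-normalization
#'   integrated weights in attribute \code{"integrated"}.
#' @examples
#' imp <- rbind(c("M", "MH", "VH", "VL"), c("M", "MH", "VH", "VL"),
#'              c("L", "H", "HVH", "L"), c("M", "HVH", "MH", "L"))
#' criteria_weights(imp)  # integrated (4.5, 6.75, 8, 2) -> (0.2118, ...)
#' @export
criteria_weights <- function(importance, expert_weights = NULL) {
  if (!is.matrix(importance)) importance <- rbind(importance)
  k <- nrow(importance)
  if (is.null(expert_weights)) expert_weights <- rep(1 / k, k)
  expert_weights <- validate_weights(expert_weights, k)
  num <- matrix(saaty_value(importance), nrow = k,
                dimnames = dimnames(importance))
  integrated <- colSums(num * expert_weights)
  if (sum(integrated) <= 0) {
    stop(phf_error("all integrated criteria weights are zero", "phf_weight_error"))
  }
  structure(integrated / sum(integrated), integrated = integrated)
}

#' Per-expert weighted numeric decision matrices
#'
#' Converts each expert's linguistic matrix to numbers via the Saaty scale
#' and multiplies by the expert's weight, so that collecting the k expert
#' values of a cell later yields a hesitant evaluation on a common scale.
#'
#' @param problem a \code{"phf_problem"} with linguistic matrices.
#' @return A named list of numeric criteria x alternatives matrices.
#' @export
weighted_numeric_matrices <- function(problem) {
  if (is.null(problem$linguistic)) {
    stop(phf_error("the problem carries no linguistic matrices", "phf_problem_error"))
  }
  out <- vector("list", length(problem$linguistic))
  names(out) <- names(problem$linguistic)
  for (q in seq_along(problem$linguistic)) {
    g <- problem$linguistic[[q]]
    num <- matrix(saaty_value(g) * problem$expert_weights[q],
                  nrow = nrow(g), dimnames = dimnames(g))
    out[[q]] <- num
  }
  out
}

#' Hesitant fuzzy group decision matrix
#'
#' Collects, for every alternative x criterion cell, the k experts'
#' weighted numeric values, sorted ascending.
#'
#' @param grids list of numeric criteria x alternatives matrices, one per
#'   expert (all of the same shape), as produced by
#'   [weighted_numeric_matrices()].
#' @param alternatives,criteria optional names; taken from the first grid's
#'   dimnames when absent.
#' @return An object of class \code{"group_hf_matrix"}: an alternatives x
#'   criteria matrix of list cells, each cell a sorted numeric vector of
#'   length k.
#' @export
group_matrix <- function(grids, alternatives = NULL, criteria = NULL) {
  dims <- unique(lapply(grids, dim))
  if (length(dims) != 1L) {
    stop(phf_error("all expert grids must have the same shape", "phf_problem_error"))
  }
  nc <- dims[[1]][1]; na <- dims[[1]][2]
  if (is.null(criteria)) criteria <- rownames(grids[[1]]) %||% paste0("C", seq_len(nc))
  if (is.null(alternatives)) alternatives <- colnames(grids[[1]]) %||% paste0("A", seq_len(na))
  cells <- matrix(vector("list", na * nc), nrow = na,
                  dimnames = list(alternatives, criteria))
  for (i in seq_len(na)) {
    for (j in seq_len(nc)) {
      cells[[i, j]] <- sort(unname(vapply(grids, function(g) g[j, i], numeric(1))))
    }
  }
  structure(cells, class = "group_hf_matrix", k = length(grids))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a hesitant fuzzy group decision matrix
#'
#' Benefit criteria are divided by the global maximum of their column
#' (across all alternatives and experts); for cost criteria the global
#' column minimum is divided by each value, so that for every criterion the
#' best raw evaluation maps to 1 and all outputs lie in (0, 1].
#'
#' @param gm a \code{"group_hf_matrix"}.
#' @param directions \code{"benefit"}/\code{"cost"} per criterion.
#' @param rounding \code{"precise"} (default) keeps full precision;
#'   \code{"paper"} rounds every normalized value half-up to 2 decimals,
#'   the convention under which the package's built-in case study
#'   reproduces its printed tables.
#' @return A \code{"group_hf_matrix"} of normalized cells.
#' @export
normalize_group_matrix <- function(gm, directions, rounding = c("precise", "paper")) {
  rounding <- match.arg(rounding)
  na <- nrow(gm); nc <- ncol(gm)
  directions <- match.arg(directions, c("benefit", "cost"), several.ok = TRUE)
  if (length(directions) != nc) {
    stop(phf_error("one direction per criterion is required", "phf_problem_error"))
  }
  out <- gm
  for (j in seq_len(nc)) {
    colvals <- unlist(gm[, j])
    if (directions[j] == "benefit") {
      mx <- max(colvals)
      if (mx <= 0) stop(phf_error("zero column maximum in a benefit criterion", "phf_problem_error"))
      f <- function(v) v / mx
    } else {
      if (any(colvals <= 0)) {
        stop(phf_error("cost criteria require strictly positive entries", "phf_problem_error"))
      }
      mn <- min(colvals)
      f <- function(v) mn / v
    }
    for (i in seq_len(na)) {
      v <- f(gm[[i, j]])
      out[[i, j]] <- if (rounding == "paper") round_half_up(v, 2) else v
    }
  }
  out
}

#' Probabilistic hesitant fuzzy decision matrix
#'
#' @param cells an alternatives x criteria matrix of \code{"phfe"} cells
#'   (a list matrix), or a list of rows, each row a list/\code{"phfs"} of
#'   PHFEs over the criteria.
#' @param alternatives,criteria optional dimension names.
#' @return An object of class \code{"phf_matrix"}.
#' @export
phf_matrix <- function(cells, alternatives = NULL, criteria = NULL) {
  if (!is.matrix(cells)) {
    rows <- cells
    na <- length(rows); nc <- length(rows[[1]])
    cells <- matrix(vector("list", na * nc), nrow = na)
    for (i in seq_len(na)) {
      if (length(rows[[i]]) != nc) {
        stop(phf_error("ragged PHF decision matrix", "phf_problem_error"))
      }
      for (j in seq_len(nc)) cells[[i, j]] <- validate_phfe(rows[[i]][[j]])
    }
    if (is.null(alternatives)) alternatives <- names(rows) %||% paste0("A", seq_len(na))
  } else {
    for (idx in seq_along(cells)) cells[[idx]] <- validate_phfe(cells[[idx]])
    if (is.null(alternatives)) alternatives <- rownames(cells) %||% paste0("A", seq_len(nrow(cells)))
  }
  if (is.null(criteria)) criteria <- colnames(cells) %||% paste0("C", seq_len(ncol(cells)))
  dimnames(cells) <- list(alternatives, criteria)
  structure(cells, class = "phf_matrix")
}

#' @export
print.phf_matrix <- function(x, digits = 2, ...) {
  cat("PHF decision matrix:", nrow(x), "alternatives x", ncol(x), "criteria\n")
  for (i in seq_len(nrow(x))) {
    cells <- vapply(seq_len(ncol(x)), function(j) {
      h <- x[[i, j]]
      paste0("{", paste0(format(h$m, digits = digits), "|",
                         format(h$p, digits = digits), collapse = ","), "}")
    }, character(1))
    cat(sprintf("  %-4s %s\n", rownames(x)[i], paste(cells, collapse = "  ")))
  }
  invisible(x)
}

#' Row of a PHF decision matrix as a PHFS
#'
#' @param pm a \code{"phf_matrix"}.
#' @param i row index or alternative name.
#' @return A \code{"phfs"} over the criteria.
#' @export
phf_row <- function(pm, i) {
  structure(pm[i, ], class = "phfs")
}

#' Group matrix to probabilistic hesitant fuzzy matrix
#'
#' Per cell, equal values among the k expert evaluations are merged and
#' assigned probability multiplicity/k, turning the hesitant fuzzy group
#' matrix into a probabilistic hesitant fuzzy decision matrix.
#'
#' @param gm a (normalized) \code{"group_hf_matrix"}.
#' @param tol merge tolerance for value equality (default 1e-9).
#' @return A \code{"phf_matrix"}.
#' @export
to_phf_matrix <- function(gm, tol = 1e-9) {
  cells <- matrix(vector("list", length(gm)), nrow = nrow(gm), dimnames = dimnames(gm))
  for (idx in seq_along(gm)) {
    v <- sort(gm[[idx]])
    k <- length(v)
    grp <- cumsum(c(TRUE, diff(v) > tol))
    mem <- vapply(split(v, grp), function(g) g[1L], numeric(1))
    prob <- as.numeric(table(grp)) / k
    cells[[idx]] <- phfe(mem, prob)
  }
  phf_matrix(cells)
}

#' Ideal alternative of a PHF decision matrix
#'
#' For every criterion the evaluation with the maximal score is selected;
#' score ties are broken by minimal deviation, and remaining ties by the
#' lowest alternative index. Alternatives are later ranked by their
#' weighted correlation with this synthetic best row.
#'
#' @param pm a \code{"phf_matrix"}.
#' @return A \code{"phfs"} over the criteria, with the contributing
#'   alternative indices in attribute \code{"source"}.
#' @export
ideal_alternative <- function(pm) {
  nc <- ncol(pm)
  ideal <- vector("list", nc)
  src <- integer(nc)
  for (j in seq_len(nc)) {
    best <- 1L
    for (i in seq_len(nrow(pm))[-1L]) {
      if (phf_compare(pm[[i, j]], pm[[best, j]]) > 0L) best <- i
    }
    ideal[[j]] <- pm[[best, j]]
    src[j] <- best
  }
  structure(ideal, class = "phfs", source = src)
}

#' Rank alternatives by weighted correlation with the ideal
#'
#' Computes the weighted information-energy correlation coefficient
#' [rho3()] between every alternative's row and the ideal alternative and
#' orders alternatives by descending coefficient. Exact coefficient ties
#' keep their input order and are annotated.
#'
#' @param pm a \code{"phf_matrix"}.
#' @param weights criteria weight vector.
#' @param ideal optionally, a precomputed ideal row ([ideal_alternative()]).
#' @param method correlation used against the ideal: \code{"rho3"}
#'   (default) or \code{"rho4"}.
#' @return An object of class \code{"phf_ranking"}: a list with
#'   \code{coefficients} (named, input order), \code{ordering} (alternative
#'   names, best first), \code{ranking} (a data.frame) and \code{ties}.
#' @export
rank_alternatives <- function(pm, weights, ideal = NULL, method = c("rho3", "rho4")) {
  method <- match.arg(method)
  weights <- validate_weights(weights, ncol(pm))
  if (is.null(ideal)) ideal <- ideal_alternative(pm)
  fun <- if (method == "rho3") rho3 else rho4
  coefs <- vapply(seq_len(nrow(pm)),
                  function(i) fun(phf_row(pm, i), ideal, weights), numeric(1))
  names(coefs) <- rownames(pm)
  o <- order(-coefs)  # stable: ties keep input order
  dup <- duplicated(coefs) | duplicated(coefs, fromLast = TRUE)
  ranking <- data.frame(alternative = names(coefs)[o],
                        coefficient = unname(coefs[o]),
                        rank = seq_along(coefs),
                        tie = dup[o],
                        row.names = NULL)
  structure(list(coefficients = coefs, ordering = names(coefs)[o],
                 ranking = ranking, ties = names(coefs)[dup],
                 ideal = ideal, method = method, weights = weights),
            class = "phf_ranking")
}

#' @export
print.phf_ranking <- function(x, ...) {
  cat("Correlation with the ideal alternative (", x$method, "):\n", sep = "")
  for (i in seq_len(nrow(x$ranking))) {
    r <- x$ranking[i, ]
    cat(sprintf("  %d. %-6s %.4f%s\n", r$rank, r$alternative, r$coefficient,
                if (r$tie) " (tie)" else ""))
  }
  cat("Ordering:", paste(x$ordering, collapse = " > "), "\n")
  invisible(x)
}

#' Run the full group decision pipeline
#'
#' Executes the correlation-based group decision procedure end to end:
#' criteria weights from the importance grid (unless explicit weights are
#' supplied), per-expert weighted numeric matrices, hesitant fuzzy group
#' matrix, benefit/cost normalization, probabilistic hesitant fuzzy group
#' matrix, ideal alternative, and the weighted-correlation ranking. When
#' the problem supplies a PHF decision matrix directly, the pipeline starts
#' at the ideal-construction step. All intermediate artifacts are returned
#' for audit.
#'
#' @param problem a \code{"phf_problem"}.
#' @param rounding \code{"precise"} (default) or \code{"paper"}; see
#'   [normalize_group_matrix()].
#' @return An object of class \code{"phf_evaluation"}: a list with
#'   \code{weights}, \code{numeric} (per-expert grids), \code{group},
#'   \code{normalized}, \code{phf} (the PHF matrix), \code{ideal},
#'   \code{coefficients} and \code{ranking}.
#' @examples
#' fx <- phf_fixture("case-study")
#' ev <- phf_evaluate(fx$problem, rounding = "paper")
#' ev$ranking$ordering  # "A3" "A2" "A1" "A4" "A5"
#' @export
phf_evaluate <- function(problem, rounding = c("precise", "paper")) {
  rounding <- match.arg(rounding)
  if (!inherits(problem, "phf_problem")) {
    stop(phf_error("expected a 'phf_problem'", "phf_problem_error"))
  }
  weights <- problem$weights
  if (is.null(weights)) {
    if (is.null(problem$importance)) {
      stop(phf_error("either explicit criteria weights or an importance grid is required",
                     "phf_problem_error"))
    }
    weights <- criteria_weights(problem$importance, problem$expert_weights)
  }
  numeric_grids <- NULL; gm <- NULL; norm <- NULL
  if (!is.null(problem$phf_matrix)) {
    pm <- problem$phf_matrix
  } else {
    numeric_grids <- weighted_numeric_matrices(problem)
    gm <- group_matrix(numeric_grids, problem$alternatives, problem$criteria)
    norm <- normalize_group_matrix(gm, problem$directions, rounding)
    pm <- to_phf_matrix(norm)
  }
  rk <- rank_alternatives(pm, weights)
  structure(list(weights = weights, numeric = numeric_grids, group = gm,
                 normalized = norm, phf = pm, ideal = rk$ideal,
                 coefficients = rk$coefficients, ranking = rk,
                 rounding = rounding),
            class = "phf_evaluation")
}

#' @export
print.phf_evaluation <- function(x, ...) {
  cat("PHF group decision evaluation (", x$rounding, " mode)\n", sep = "")
  cat("Criteria weights:", paste(format(as.numeric(x$weights), digits = 4), collapse = ", "), "\n")
  print(x$ranking)
  invisible(x)
}
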