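#' Read and write PHFSs as JSON
#'
#' A PHFE is serialized as an array of \code{{"m": <float>, "p": <float>}}
#' objects and a PHFS as an array of such arrays.
#'
#' @param path file path.
#' @return For the readers, a \code{"phfs"}; the writers return the path
#'   invisibly.
#' @export
read_phfs_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  parse_phfs(raw)
}

parse_phfe <- function(entries) {
  phfe(vapply(entries, function(e) as.numeric(e$m), numeric(1)),
       vapply(entries, function(e) as.numeric(e$p), numeric(1)))
}

parse_phfs <- function(raw) {
  phfs(lapply(raw, parse_phfe))
}

#' @rdname read_phfs_json
#' @param A a \code{"phfs"}.
#' @export
write_phfs_json <- function(A, path) {
  out <- lapply(A, function(h) {
    lapply(seq_along(h$m), function(j) list(m = h$m[j], p = h$p[j]))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write PHFSs as CSV
#'
#' One row per universe item; cells are \code{"gamma|p"} pairs separated by
#' semicolons, e.g. \code{0.2|0.6;0.8|0.4}.
#'
#' @param path file path.
#' @param A a \code{"phfs"} (writer).
#' @return A \code{"phfs"} (reader); the writer returns the path invisibly.
#' @export
read_phfs_csv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  phfs(lapply(lines, function(line) {
    cells <- strsplit(trimws(line), ";", fixed = TRUE)[[1]]
    parts <- vapply(cells, function(cell) {
      mp <- strsplit(trimws(cell), "|", fixed = TRUE)[[1]]
      if (length(mp) != 2L) {
        stop(phf_error(sprintf("malformed CSV cell '%s' (expected 'gamma|p')", cell),
                       "phf_parse_error"))
      }
      as.numeric(mp)
    }, numeric(2))
    phfe(parts[1, ], parts[2, ])
  }))
}

#' @rdname read_phfs_csv
#' @export
write_phfs_csv <- function(A, path) {
  lines <- vapply(A, function(h) {
    paste0(format(h$m, digits = 15, trim = TRUE), "|",
           format(h$p, digits = 15, trim = TRUE), collapse = ";")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a group decision problem from JSON
#'
#' Expected schema:
#' \preformatted{
#' {"alternatives": ["A1", ...],
#'  "criteria": [{"name": "C1", "direction": "benefit"}, ...],
#'  "experts": [{"name": "D1", "weight": 0.25}, ...],
#'  "matrices": {"D1": [["VH", ...], ...], ...},   # rows = criteria
#'  "importance": {"D1": ["M", ...], ...}          # or "weights": [...]
#'  "phf_matrix": {"A1": [[{"m":..., "p":...}, ...], ...]}  # alternative
#' }
#' }
#' Either linguistic \code{matrices} or a direct \code{phf_matrix} must be
#' present.
#'
#' @param path file path.
#' @return A \code{"phf_problem"}.
#' @export
read_problem_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  need <- function(field) {
    if (is.null(raw[[field]])) {
      stop(phf_error(sprintf("problem JSON lacks required field '%s'", field),
                     "phf_parse_error"))
    }
    raw[[field]]
  }
  alternatives <- as.character(unlist(need("alternatives")))
  criteria <- vapply(need("criteria"), function(cr) as.character(cr$name), character(1))
  directions <- vapply(raw$criteria, function(cr) as.character(cr$direction), character(1))

  expert_weights <- NULL; linguistic <- NULL; importance <- NULL
  if (!is.null(raw$experts)) {
    expert_weights <- vapply(raw$experts, function(e) as.numeric(e$weight), numeric(1))
    names(expert_weights) <- vapply(raw$experts, function(e) as.character(e$name), character(1))
  }
  if (!is.null(raw$matrices)) {
    linguistic <- lapply(raw$matrices, function(rows) {
      m <- do.call(rbind, lapply(rows, function(r) as.character(unlist(r))))
      if (ncol(m) != length(alternatives) || nrow(m) != length(criteria)) {
        stop(phf_error("linguistic matrix shape does not match alternatives/criteria",
                       "phf_parse_error"))
      }
      dimnames(m) <- list(criteria, alternatives)
      m
    })
    if (!is.null(expert_weights)) linguistic <- linguistic[names(expert_weights)]
  }
  if (!is.null(raw$importance)) {
    importance <- do.call(rbind, lapply(raw$importance, function(r) as.character(unlist(r))))
    colnames(importance) <- criteria
  }
  weights <- if (!is.null(raw$weights)) as.numeric(unlist(raw$weights))
  pm <- NULL
  if (!is.null(raw$phf_matrix)) {
    rows <- lapply(raw$phf_matrix, function(r) lapply(r, parse_phfe))
    pm <- phf_matrix(rows, alternatives = names(raw$phf_matrix), criteria = criteria)
  }
  phf_problem(alternatives, criteria, directions,
              linguistic = linguistic, expert_weights = expert_weights,
              importance = importance, weights = weights, phf_matrix = pm)
}

#' Seeded random PHFS generator
#'
#' Draws a PHFS for property testing: \code{n} elements, each with a
#' uniformly chosen number of entries between 1 and \code{max_len},
#' memberships uniform on [0, 1] and probabilities either drawn uniformly
#' and normalized to sum to 1 (\code{"uniform-dirichlet"}) or all equal
#' (\code{"equal"}). A fixed seed gives identical output.
#'
#' @param n universe size.
#' @param max_len maximum entries per element.
#' @param scheme probability scheme.
#' @param seed optional integer seed; when supplied, the global RNG state
#'   is restored on exit.
#' @return A \code{"phfs"}.
#' @export
random_phfs <- function(n, max_len = 4, scheme = c("uniform-dirichlet", "equal"),
                        seed = NULL) {
  scheme <- match.arg(scheme)
  if (n < 1 || max_len < 1) {
    stop(phf_error("random_phfs needs n >= 1 and max_len >= 1", "phf_config_error"))
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  phfs(lapply(seq_len(n), function(i) {
    l <- sample.int(max_len, 1L)
    m <- runif(l)
    p <- if (scheme == "equal") rep(1 / l, l) else {
      u <- runif(l)
      u / sum(u)
    }
    phfe(m, p)
  }))
}
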