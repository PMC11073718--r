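#' Built-in worked examples and case-study fixtures
#'
#' The package ships the worked examples it documents as ready-made
#' fixtures: small PHFE/PHFS pairs illustrating the score, deviation and
#' correlation machinery, the orphan-drug group decision case study
#' (five narcolepsy treatments, four medical experts, four criteria), its
#' weight-sensitivity and rank-reversal variants, and two decision matrices
#' from the comparison literature (Wang-Li mean correlation, Liu-Guan mixed
#' correlation, Chen et al. hesitant-fuzzy correlation). Every fixture
#' carries the values the package's own functions reproduce, plus a note
#' describing its role.
#'
#' @param id fixture identifier; see [phf_fixtures()] for the list.
#' @return A list with at least \code{id}, \code{note}, a payload
#'   (PHFE/PHFS objects, a \code{"phf_problem"} or a \code{"phf_matrix"})
#'   and an \code{expected} list of reference values.
#' @examples
#' fx <- phf_fixture("score-deviation")
#' phf_score(fx$h1)  # 0.44
#' @export
phf_fixture <- function(id) {
  builders <- fixture_builders()
  if (!id %in% names(builders)) {
    stop(phf_error(sprintf("unknown fixture '%s'; see phf_fixtures()", id),
                   "phf_fixture_error"))
  }
  c(list(id = id), builders[[id]]())
}

#' @rdname phf_fixture
#' @return For \code{phf_fixtures()}, a character vector of identifiers.
#' @export
phf_fixtures <- function() names(fixture_builders())

# Table 16-style matrix shared by the case study, the sensitivity analysis
# and the rank-reversal variants.
case_phf_rows <- function() {
  list(
    A1 = list(phfe(c(0.89, 1),          c(0.5, 0.5)),
              phfe(c(0.6, 0.75),        c(0.25, 0.75)),
              phfe(c(0.75, 0.88),       c(0.25, 0.75)),
              phfe(c(0.78, 1),          c(0.5, 0.5))),
    A2 = list(phfe(c(0.22, 0.33, 0.44), c(0.25, 0.25, 0.5)),
              phfe(c(0.33, 0.43, 0.5, 0.6), c(0.25, 0.25, 0.25, 0.25)),
              phfe(0.88, 1),
              phfe(c(0.56, 0.67, 0.44), c(0.25, 0.25, 0.5))),
    A3 = list(phfe(c(0.67, 0.78),       c(0.25, 0.75)),
              phfe(c(0.33, 0.43),       c(0.5, 0.5)),
              phfe(0.63, 1),
              phfe(c(0.11, 0.22),       c(0.5, 0.5))),
    A4 = list(phfe(c(0.67, 0.78),       c(0.5, 0.5)),
              phfe(c(0.75, 1),          c(0.5, 0.5)),
              phfe(c(0.38, 0.5),        c(0.5, 0.5)),
              phfe(c(0.78, 0.67),       c(0.25, 0.75))),
    A5 = list(phfe(0.78, 1),
              phfe(c(0.43, 0.5),        c(0.5, 0.5)),
              phfe(c(0.75, 1, 0.88),    c(0.25, 0.25, 0.5)),
              phfe(c(0.44, 0.56),       c(0.5, 0.5))))
}

case_weights <- c(0.21, 0.31, 0.39, 0.09)

case_linguistic <- function() {
  alt <- paste0("A", 1:5); crit <- paste0("C", 1:4)
  g <- function(...) matrix(c(...), nrow = 4, byrow = TRUE,
                            dimnames = list(crit, alt))
  list(
    D1 = g("VH", "L",   "MH", "H",  "H",
           "M",  "M",   "H",  "ML", "H",
           "H",  "H",   "M",  "ML", "MH",
           "VH", "ML",  "VL", "MH", "ML"),
    D2 = g("VH", "VLL", "H",  "H",  "H",
           "ML", "MH",  "H",  "ML", "MH",
           "H",  "H",   "M",  "ML", "H",
           "VH", "ML",  "VL", "H",  "ML"),
    D3 = g("HVH", "ML", "H",  "MH", "H",
           "ML",  "H",  "VH", "L",  "MH",
           "H",   "H",  "M",  "L",  "H",
           "H",   "M",  "VLL", "MH", "M"),
    D4 = g("HVH", "ML", "H",  "MH", "H",
           "ML",  "VH", "VH", "L",  "H",
           "MH",  "H",  "M",  "L",  "HVH",
           "H",   "MH", "VLL", "MH", "M"))
}

case_importance <- function() {
  matrix(c("M", "MH", "VH",  "VL",
           "M", "MH", "VH",  "VL",
           "L", "H",  "HVH", "L",
           "M", "HVH", "MH", "L"),
         nrow = 4, byrow = TRUE,
         dimnames = list(paste0("D", 1:4), paste0("C", 1:4)))
}

fixture_builders <- function() list(

  "score-deviation" = function() {
    list(note = "two PHFEs with equal score 0.44 separated by the deviation function",
         h1 = phfe(c(0.2, 0.8), c(0.6, 0.4)),
         h2 = phfe(c(0.6, 0.4), c(0.2, 0.8)),
         expected = list(score = 0.44, deviation1 = 0.0864, deviation2 = 0.0064,
                         comparison = -1L))
  },

  "energy-pair" = function() {
    # B's second element uses the computation-consistent values
    # (0.2|0.4, 0.3|0.1, 0.5|0.5).
    list(note = "worked pair for the information-energy correlation, incl. pessimistic padding",
         A = phfs(phfe(c(0.5, 0.8, 0.7), c(0.4, 0.3, 0.3)),
                  phfe(c(0.1, 0.3, 0.6), c(0.5, 0.3, 0.2)),
                  phfe(c(0.2, 0.3), c(0.7, 0.3))),
         B = phfs(phfe(c(0.4, 0.5), c(0.3, 0.7)),
                  phfe(c(0.2, 0.3, 0.5), c(0.4, 0.1, 0.5)),
                  phfe(c(0.3, 0.8, 0.7), c(0.2, 0.1, 0.7))),
         expected = list(energy_a = 0.0694, energy_b = 0.1751,
                         cross = 0.0746, rho1 = 0.6764))
  },

  "three-set" = function() {
    list(note = "three PHFSs with identical per-element means: the mean/variance baseline collapses to 1, the information-energy coefficient distinguishes them",
         A = phfs(phfe(c(0.3, 0.5), c(1/2, 1/2)),
                  phfe(c(0.3, 0.6, 0.9), c(1/3, 1/3, 1/3)),
                  phfe(c(0.1, 0.2, 0.8, 0.9), c(1/4, 1/4, 1/4, 1/4))),
         B = phfs(phfe(c(0.1, 0.7), c(1/2, 1/2)),
                  phfe(c(0.2, 0.7, 0.9), c(1/3, 1/3, 1/3)),
                  phfe(c(0.3, 0.5, 0.7), c(1/3, 1/3, 1/3))),
         C = phfs(phfe(c(0.2, 0.3, 0.7), c(1/3, 1/3, 1/3)),
                  phfe(c(0.5, 0.7), c(1/2, 1/2)),
                  phfe(c(0.4, 0.5, 0.6), c(1/3, 1/3, 1/3))),
         expected = list(energy_a = 0.1126, energy_b = 0.1429, energy_c = 0.1440,
                         rho1_ab = 0.9302, rho1_ac = 0.7646, rho1_bc = 0.7850,
                         song = 1))
  },

  "case-study" = function() {
    list(note = "orphan-drug evaluation: 5 narcolepsy treatments, 4 equally weighted medical experts, criteria safety/effectiveness(cost)/economy/social value; printed 2-dp weights pinned",
         problem = phf_problem(
           alternatives = paste0("A", 1:5),
           criteria = paste0("C", 1:4),
           directions = c("benefit", "cost", "benefit", "benefit"),
           linguistic = case_linguistic(),
           importance = case_importance(),
           weights = case_weights),
         expected = list(
           integrated = c(4.5, 6.75, 8, 2),
           weights_exact = c(4.5, 6.75, 8, 2) / 21.25,
           coefficients = c(A1 = 0.7708, A2 = 0.8932, A3 = 0.9589,
                            A4 = 0.6794, A5 = 0.4699),
           ordering = c("A3", "A2", "A1", "A4", "A5")))
  },

  "case-study-phf" = function() {
    list(note = "the case study's PHF group decision matrix and criteria weights, entered directly",
         matrix = phf_matrix(case_phf_rows(), criteria = paste0("C", 1:4)),
         weights = case_weights,
         expected = list(
           ideal = phfs(phfe(c(0.89, 1), c(0.5, 0.5)),
                        phfe(c(0.75, 1), c(0.5, 0.5)),
                        phfe(0.88, 1),
                        phfe(c(0.78, 1), c(0.5, 0.5))),
           coefficients = c(A1 = 0.7708, A2 = 0.8932, A3 = 0.9589,
                            A4 = 0.6794, A5 = 0.4699),
           ordering = c("A3", "A2", "A1", "A4", "A5")))
  },

  "sensitivity" = function() {
    list(note = "weight-sensitivity scenarios on the case-study PHF matrix",
         matrix = phf_matrix(case_phf_rows(), criteria = paste0("C", 1:4)),
         scenarios = list(
           w1 = c(0.1, 0.2, 0.3, 0.4),
           w2 = c(0.2, 0.1, 0.3, 0.4),
           w3 = c(0.3, 0.2, 0.4, 0.1),
           w4 = c(0.4, 0.3, 0.2, 0.1)),
         expected = list(
           coefficients = rbind(
             w1 = c(0.8031, 0.8721, 0.9218, 0.7149, 0.5703),
             w2 = c(0.8092, 0.8738, 0.9153, 0.7199, 0.5089),
             w3 = c(0.7740, 0.8981, 0.9555, 0.6805, 0.4402),
             w4 = c(0.8432, 0.8080, 0.9240, 0.7912, 0.4805)),
           orderings = list(
             w1 = c("A3", "A2", "A1", "A4", "A5"),
             w2 = c("A3", "A2", "A1", "A4", "A5"),
             w3 = c("A3", "A2", "A1", "A4", "A5"),
             w4 = c("A3", "A1", "A2", "A4", "A5"))))
  },

  "rank-reversal-A6" = function() {
    rows <- case_phf_rows()
    rows$A6 <- list(phfe(c(0.63, 0.76), c(0.25, 0.75)),
                    phfe(c(0.3, 0.4), c(0.5, 0.5)),
                    phfe(0.6, 1),
                    phfe(c(0.1, 0.2), c(0.5, 0.5)))
    list(note = "rank-reversal probe: a sixth alternative slightly inferior to the best one",
         matrix = phf_matrix(rows, criteria = paste0("C", 1:4)),
         weights = case_weights,
         expected = list(ordering = c("A3", "A6", "A2", "A1", "A4", "A5")))
  },

  "rank-reversal-A6plus" = function() {
    rows <- case_phf_rows()
    rows[["A6plus"]] <- list(phfe(0.75, 1),
                             phfe(c(0.4, 0.45), c(0.5, 0.5)),
                             phfe(c(0.7, 0.8, 0.85), c(0.25, 0.25, 0.5)),
                             phfe(c(0.4, 0.5), c(0.5, 0.5)))
    list(note = "rank-reversal probe: a sixth alternative slightly inferior to the worst one",
         matrix = phf_matrix(rows, criteria = paste0("C", 1:4)),
         weights = case_weights,
         expected = list(ordering = c("A3", "A2", "A1", "A4", "A5", "A6plus")))
  },

  "wang-li" = function() {
    rows <- list(
      A1 = list(phfe(c(0.7, 0.5), c(0.25, 0.75)),
                phfe(c(0.8, 0.6, 0.7), c(0.1, 0.25, 0.65)),
                phfe(c(0.3, 0.6, 0.4), c(0.15, 0.25, 0.6)),
                phfe(c(0.3, 0.4, 0.6, 0.7), c(0.125, 0.125, 0.25, 0.5)),
                phfe(c(0.3, 0.4, 0.5, 0.8), c(0.25, 0.25, 0.25, 0.25))),
      A2 = list(phfe(c(0.2, 0.4, 0.3), c(0.1, 0.25, 0.65)),
                phfe(c(0.4, 0.5), c(0.5, 0.5)),
                phfe(c(0.6, 0.4, 0.5, 0.8), c(0.125, 0.25, 0.375, 0.25)),
                phfe(c(0.4, 0.6, 0.7), c(0.25, 0.375, 0.375)),
                phfe(c(0.4, 0.6), c(0.25, 0.75))),
      A3 = list(phfe(c(0.4, 0.7, 0.6), c(0.25, 0.3, 0.45)),
                phfe(c(0.4, 0.6, 0.5), c(0.25, 0.25, 0.5)),
                phfe(c(0.2, 0.3, 0.5, 0.6), c(0.25, 0.25, 0.25, 0.25)),
                phfe(c(0.1, 0.5, 0.3), c(0.25, 0.25, 0.5)),
                phfe(c(0.6, 0.4, 0.7), c(0.125, 0.5, 0.375))),
      A4 = list(phfe(c(0.2, 0.3, 0.4, 0.6), c(0.25, 0.25, 0.25, 0.25)),
                phfe(c(0.4, 0.3, 0.6), c(0.25, 0.5, 0.25)),
                phfe(c(0.3, 0.4, 0.5), c(0.25, 0.25, 0.5)),
                phfe(c(0.4, 0.6, 0.5), c(0.175, 0.25, 0.575)),
                phfe(c(0.2, 0.4, 0.5, 0.7), c(0.25, 0.125, 0.375, 0.25))))
    # The reference ideal row is pinned as published: its C3 entry is A1's
    # cell even though A2's C3 cell has the higher score, so it is an input
    # here, not the output of ideal_alternative(). The published A4
    # coefficient (0.7706) does not recompute under the stated formulas
    # (0.7769 does); only A1-A3 are reproducible reference values.
    list(note = "comparison example of the mean-correlation (Wang-Li) literature, re-evaluated with the information-energy coefficient; published ideal pinned as input",
         matrix = phf_matrix(rows, criteria = paste0("C", 1:5)),
         weights = c(0.19, 0.21, 0.19, 0.20, 0.21),
         ideal = phfs(phfe(c(0.4, 0.7, 0.6), c(0.25, 0.3, 0.45)),
                      phfe(c(0.8, 0.6, 0.7), c(0.1, 0.25, 0.65)),
                      phfe(c(0.3, 0.6, 0.4), c(0.15, 0.25, 0.6)),
                      phfe(c(0.4, 0.6, 0.7), c(0.25, 0.375, 0.375)),
                      phfe(c(0.4, 0.6), c(0.25, 0.75))),
         expected = list(
           coefficients = c(A1 = 0.7755, A2 = 0.9092, A3 = 0.8626, A4 = 0.7706),
           reproducible = c("A1", "A2", "A3"),
           ordering = c("A2", "A3", "A1", "A4")))
  },

  "liu-guan" = function() {
    rows <- list(
      A1 = list(phfe(c(0.76, 0.55, 0.65, 0.8), c(0.1, 0.15, 0.25, 0.5)),
                phfe(c(0.2, 0.4, 0.3, 0.65, 0.75), c(0.05, 0.125, 0.325, 0.25, 0.25)),
                phfe(c(0.94, 0.8, 0.75, 0.55), c(0.1, 0.15, 0.25, 0.5))),
      A2 = list(phfe(c(0.4, 0.58, 0.69, 0.95), c(0.25, 0.25, 0.25, 0.25)),
                phfe(c(0.6, 0.8, 0.35, 0.65, 0.7), c(0.075, 0.075, 0.25, 0.25, 0.35)),
                phfe(c(0.25, 0.45, 0.65), c(0.25, 0.375, 0.375))),
      A3 = list(phfe(c(0.3, 0.68, 0.5, 0.6), c(0.1, 0.25, 0.35, 0.3)),
                phfe(c(0.55, 0.66, 0.45, 0.56, 0.85), c(0.125, 0.125, 0.25, 0.25, 0.25)),
                phfe(c(0.45, 0.55, 0.68, 0.75), c(0.25, 0.25, 0.25, 0.25))),
      A4 = list(phfe(c(0.15, 0.37, 0.4, 0.6, 0.73), c(0.1, 0.15, 0.25, 0.25, 0.25)),
                phfe(c(0.62, 0.55, 0.66, 0.48), c(0.1, 0.25, 0.25, 0.4)),
                phfe(c(0.5, 0.7, 0.38, 0.75, 0.85), c(0.125, 0.125, 0.25, 0.25, 0.25))))
    list(note = "comparison example of the mixed-correlation (Liu-Guan) literature; only the best/worst endpoints are treated as reference results",
         matrix = phf_matrix(rows, criteria = paste0("C", 1:3)),
         weights = c(0.39, 0.26, 0.35),
         expected = list(best = "A1", worst = "A4"))
  },

  "hfs-comparison" = function() {
    A <- list(A1 = list(c(0.89, 1), c(0.60, 0.75), c(0.75, 0.88), c(0.78, 1)),
              A2 = list(c(0.22, 0.33, 0.44), c(0.33, 0.43, 0.50, 0.60), 0.88,
                        c(0.44, 0.56, 0.67)),
              A3 = list(c(0.67, 0.78), c(0.33, 0.43), 0.63, c(0.11, 0.22)),
              A4 = list(c(0.67, 0.78), c(0.75, 1.00), c(0.38, 0.50), c(0.67, 0.78)),
              A5 = list(0.78, c(0.43, 0.50), c(0.75, 0.88, 1.00), c(0.44, 0.56)))
    ideal <- list(c(0.89, 1), c(0.75, 1), c(0.75, 0.88), c(0.78, 1))
    list(note = "the case-study matrix with probabilities stripped: plain hesitant-fuzzy baseline; only the first alternative's coefficient is a pinned reference value",
         rows = A, ideal = ideal,
         expected = list(rho_a1 = 0.9943,
                         ordering = c("A1", "A4", "A5", "A3", "A2")))
  }
)
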