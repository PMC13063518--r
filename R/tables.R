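#' Reference function-assessment measurements
#'
#' The measured IC ratios and final bite forces of the three study subjects
#' (Class I volunteer; Class II and Class III orthognathic-surgery patients
#' before and after surgery), for the left and right unilateral bite tasks.
#' These are measured model inputs, used here to recompute the derived
#' scaling-stress table.
#'
#' @return A data frame with columns `case`, `side`, `ic_temporalis`,
#'   `ic_masseter`, `final_bite_force_N`.
#' @export
reference_function_table <- function() {
  cases <- c("Class I", "Class II pre-op", "Class II post-op",
             "Class III pre-op", "Class III post-op")
  data.frame(
    case = rep(cases, each = 2),
    side = rep(c("left", "right"), times = 5),
    ic_temporalis = c(1.52, 0.71, 1.75, 0.62, 1.07, 0.61,
                      0.96, 0.41, 0.69, 1.37),
    ic_masseter = c(1.43, 1.33, 1.69, 0.34, 0.97, 1.57,
                    1.34, 1.07, 0.71, 1.00),
    final_bite_force_N = c(51.73, 48.43, 29.10, 39.20, 56.36, 54.35,
                           49.22, 35.16, 72.26, 61.85),
    stringsAsFactors = FALSE
  )
}

#' Reference morphometric measurements
#'
#' Measured condylar areas (LCA/RCA, mm^2) and biting arms (LIBA/LCBA/RIBA/
#' RCBA, mm) of the three study subjects. LIBA/RIBA are the ipsilateral
#' biting arms for left/right biting, LCBA/RCBA the contralateral ones.
#'
#' @return A data frame with one row per case.
#' @export
reference_morpho_table <- function() {
  data.frame(
    case = c("Class I", "Class II pre-op", "Class II post-op",
             "Class III pre-op", "Class III post-op"),
    LCA = c(119.1, 113.8, 112.3, 135.7, 137.1),
    RCA = c(91.0, 147.5, 109.0, 150.7, 141.8),
    LIBA = c(82.2, 76.2, 80.7, 94.7, 88.7),
    LCBA = c(103.8, 94.6, 100.1, 113.9, 109.6),
    RIBA = c(83.6, 74.3, 82.2, 94.4, 90.4),
    RCBA = c(99.3, 92.6, 97.5, 111.1, 106.3),
    stringsAsFactors = FALSE
  )
}

#' Recompute the scaling-stress table
#'
#' For every case and bite side, the scaling stress of each disc is the
#' task's final bite force divided by the condylar area on that disc's side.
#' With the default reference inputs this reproduces the printed
#' scaling-stress table after 2-decimal rounding.
#'
#' @param fun_table Function-assessment table, default
#'   [reference_function_table()].
#' @param morpho_table Morphometrics table, default
#'   [reference_morpho_table()].
#' @param digits Half-up rounding applied to the output (default 2, the
#'   printed precision); `NA` keeps full precision.
#' @return A data frame with columns `case`, `side`, `left_disc_MPa`,
#'   `right_disc_MPa`.
#' @export
scaling_stress_table <- function(fun_table = reference_function_table(),
                                 morpho_table = reference_morpho_table(),
                                 digits = 2) {
  m <- morpho_table[match(fun_table$case, morpho_table$case), ]
  left <- scaling_stress(fun_table$final_bite_force_N, m$LCA)
  right <- scaling_stress(fun_table$final_bite_force_N, m$RCA)
  if (!is.na(digits)) {
    left <- round_half_up(left, digits)
    right <- round_half_up(right, digits)
  }
  data.frame(case = fun_table$case, side = fun_table$side,
             left_disc_MPa = left, right_disc_MPa = right,
             stringsAsFactors = FALSE)
}

#' Morphometric differences against the Class I reference
#'
#' Case-minus-Class-I differences for every measured field, computed at full
#' precision and rounded half-up to the printed 1-decimal precision.
#'
#' @param morpho_table Morphometrics table, default
#'   [reference_morpho_table()].
#' @param reference_case Name of the reference row (default `"Class I"`).
#' @param digits Rounding (default 1); `NA` for full precision.
#' @return A data frame of differences, one row per non-reference case.
#' @export
morpho_difference_table <- function(morpho_table = reference_morpho_table(),
                                    reference_case = "Class I", digits = 1) {
  ref <- morpho_table[morpho_table$case == reference_case, , drop = FALSE]
  if (nrow(ref) != 1) stop("reference case not found")
  rows <- morpho_table[morpho_table$case != reference_case, , drop = FALSE]
  num <- setdiff(names(morpho_table), "case")
  out <- rows
  for (f in num) {
    d <- rows[[f]] - ref[[f]]
    out[[f]] <- if (is.na(digits)) d else round_half_up(d, digits)
  }
  out
}
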