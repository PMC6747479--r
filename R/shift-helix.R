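.check_shift_table <- function(tbl, arg = "shift table") {
  need <- c("residue_number", "residue_type", "atom", "shift")
  stopifnot(is.data.frame(tbl))
  if (!all(need %in% names(tbl))) {
    abort(paste0(arg, " must have columns ", paste(need, collapse = ", ")),
          class = "micellr_validation_error")
  }
  if (any(!is.finite(tbl$shift))) {
    abort("chemical shifts must be finite", class = "micellr_validation_error")
  }
  invisible(tbl)
}

#' Chemical-shift perturbation between two media
#'
#' Per-residue signed shift differences `delta_b - delta_a` for one atom
#' type (negative = upfield in medium b relative to medium a). Residues
#' present in only one table are reported with `NA` difference and
#' `missing = TRUE`, never silently treated as zero.
#'
#' @param table_a,table_b Shift tables: data frames with columns
#'   `residue_number`, `residue_type`, `atom`, `shift` (ppm).
#' @param atom Atom label to compare (default `"HN"`, the amide proton).
#' @return A tibble with `residue_number`, `residue_type`, `shift_a`,
#'   `shift_b`, `delta` (ppm) and `missing`, ordered by residue number.
#' @export
csp <- function(table_a, table_b, atom = "HN") {
  .check_shift_table(table_a, "table_a")
  .check_shift_table(table_b, "table_b")
  a <- dplyr::filter(table_a, .data$atom == !!atom)
  b <- dplyr::filter(table_b, .data$atom == !!atom)
  if (nrow(a) == 0 || nrow(b) == 0) {
    abort(paste0("atom '", atom, "' absent from one of the tables"),
          class = "micellr_validation_error")
  }
  joined <- dplyr::full_join(
    dplyr::select(a, "residue_number", "residue_type", shift_a = "shift"),
    dplyr::select(b, "residue_number", residue_type_b = "residue_type",
                  shift_b = "shift"),
    by = "residue_number"
  )
  if (!any(!is.na(joined$shift_a) & !is.na(joined$shift_b))) {
    abort("no residues overlap between the two tables",
          class = "micellr_empty_overlap_error")
  }
  joined |>
    dplyr::mutate(
      residue_type = dplyr::coalesce(.data$residue_type, .data$residue_type_b),
      delta = .data$shift_b - .data$shift_a,
      missing = is.na(.data$delta)
    ) |>
    dplyr::select("residue_number", "residue_type", "shift_a", "shift_b",
                  "delta", "missing") |>
    dplyr::arrange(.data$residue_number)
}

#' Combined amide chemical-shift perturbation
#'
#' Magnitude CSP combining 1H and 15N differences as
#' `sqrt(delta_H^2 + (delta_N / 5)^2)`; offered as an option beside the
#' default signed single-atom comparison of [csp()].
#'
#' @inheritParams csp
#' @param atom_h,atom_n Atom labels of the proton and nitrogen shifts.
#' @return A tibble with `residue_number`, `delta_h`, `delta_n`,
#'   `csp_combined` (ppm).
#' @export
csp_combined <- function(table_a, table_b, atom_h = "HN", atom_n = "N") {
  h <- csp(table_a, table_b, atom_h)
  n <- csp(table_a, table_b, atom_n)
  dplyr::inner_join(
    dplyr::select(h, "residue_number", "residue_type", delta_h = "delta"),
    dplyr::select(n, "residue_number", delta_n = "delta"),
    by = "residue_number"
  ) |>
    dplyr::mutate(csp_combined = sqrt(.data$delta_h^2 + (.data$delta_n / 5)^2))
}

.hydrophobic_default <- c("A", "C", "F", "I", "L", "M", "V", "W")
.aa_letters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Helical-wheel projection of a peptide sequence
#'
#' Places each residue on an ideal helical wheel: residue `i` sits at
#' azimuthal angle `((i - start) * rotation) mod 360`, with a default
#' per-residue rotation of 100 degrees (3.6 residues per alpha-helical
#' turn). Residues are classified `hydrophobic` or `hydrophilic` by
#' membership in `hydrophobic_set`.
#'
#' @param sequence One-letter amino-acid string.
#' @param start_residue Number of the first residue (sets the numbering
#'   only; angles depend on position in the sequence).
#' @param rotation Per-residue rotation, degrees.
#' @param hydrophobic_set Residue letters classed as hydrophobic.
#' @return A tibble of class `helical_wheel`: `residue_number`,
#'   `residue_type`, `angle` (degrees, `[0, 360)`), `face`.
#' @export
#' @examples
#' helical_wheel("PLIACILLLSMNST", start_residue = 258)
helical_wheel <- function(sequence, start_residue = 1, rotation = 100,
                          hydrophobic_set = .hydrophobic_default) {
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) > 0)
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(res), .aa_letters)
  if (length(bad) > 0) {
    abort(paste0("invalid residue letter(s): ", paste(bad, collapse = ", ")),
          class = "micellr_parse_error")
  }
  idx <- seq_along(res)
  out <- tibble::tibble(
    residue_number = start_residue + idx - 1,
    residue_type = res,
    angle = ((idx - 1) * rotation) %% 360,
    face = ifelse(res %in% hydrophobic_set, "hydrophobic", "hydrophilic")
  )
  class(out) <- c("helical_wheel", class(out))
  out
}

#' Amphipathicity of a helical wheel
#'
#' Circular mean resultant length of the hydrophobic residues' wheel
#' angles: 1 when all hydrophobic residues sit at one azimuth, near 0
#' when they are spread uniformly around the helix. A wheel is flagged
#' amphipathic when the resultant length exceeds `threshold` (heuristic
#' default 0.4).
#'
#' @param wheel A [helical_wheel()] tibble.
#' @param threshold Resultant-length threshold for the amphipathic flag.
#' @return A list with `resultant_length`, `mean_angle` (degrees, the
#'   centre of the hydrophobic face), `n_hydrophobic` and `amphipathic`.
#' @export
amphipathicity <- function(wheel, threshold = 0.4) {
  stopifnot(inherits(wheel, "helical_wheel"))
  ang <- wheel$angle[wheel$face == "hydrophobic"] * pi / 180
  if (length(ang) == 0) {
    return(list(resultant_length = 0, mean_angle = NA_real_,
                n_hydrophobic = 0L, amphipathic = FALSE))
  }
  cx <- mean(cos(ang)); sx <- mean(sin(ang))
  r <- sqrt(cx^2 + sx^2)
  list(resultant_length = r,
       mean_angle = (atan2(sx, cx) * 180 / pi) %% 360,
       n_hydrophobic = length(ang),
       amphipathic = r > threshold)
}
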