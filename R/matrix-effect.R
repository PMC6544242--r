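#' Matuszewski matrix effect, extraction recovery and process efficiency
#'
#' Computes the three-set statistics per analyte, concentration level and
#' matrix class, from peak areas (or, with `normalized = TRUE`, from
#' analyte/ISTD area ratios):
#' * the reference is the mean response of the neat standards (set A, >= 3
#'   replicates per level);
#' * the matrix effect is each post-extraction-spiked replicate (set B) as a
#'   percentage of the set A mean (B/A in %), reported as deviation from 100;
#' * the extraction recovery is the per-donor mean of the pre-extraction
#'   spiked samples (set C) as a percentage of the same donor's set B mean
#'   (C/B in %) -- pairing is per donor because replicate-level pairing
#'   across separately processed samples is physically undefined;
#' * the process efficiency is each set C replicate as a percentage of the
#'   set A mean (C/A in %).
#'
#' With `by = "donor"` all three statistics are computed from per-donor mean
#' responses, in which case PE = ME x ER / 100 holds exactly.
#'
#' Regular and lipemic donors are summarized separately; variability is the
#' RSD across the replicate (or donor) values within a matrix class.
#'
#' @param sets measurement tibble holding roles `setA`, `setB`, `setC` with
#'   columns `analyte`, `nominal_conc`, `donor`, `matrix` (matrix class for
#'   B/C donors), `peak_area`, `istd_area`.
#' @param normalized compute IS-normalized variants (areas replaced by
#'   analyte/ISTD ratios).
#' @param by `"replicate"` (conventional; ME and PE use each replicate) or
#'   `"donor"` (all statistics on per-donor means).
#' @return Tibble with one row per analyte x level x matrix class:
#'   `me_mean_deviation`, `me_rsd`, `er_mean`, `er_rsd`, `pe_mean`,
#'   `pe_rsd`, replicate counts, and the `normalized` flag.
#' @export
compute_me_er_pe <- function(sets, normalized = FALSE,
                             by = c("replicate", "donor")) {
  by <- match.arg(by)
  sets <- tibble::as_tibble(sets)
  stopifnot(all(c("role", "analyte", "nominal_conc", "donor", "matrix",
                  "peak_area", "istd_area") %in% names(sets)))
  sets$resp <- if (normalized) sets$peak_area / sets$istd_area
               else sets$peak_area
  a <- dplyr::filter(sets, .data$role == "setA")
  b <- dplyr::filter(sets, .data$role == "setB")
  cc <- dplyr::filter(sets, .data$role == "setC")
  if (nrow(a) == 0L || nrow(b) == 0L || nrow(cc) == 0L) {
    stop("sets A, B and C must all be present")
  }
  missing_pair <- setdiff(unique(b$donor), unique(cc$donor))
  if (length(missing_pair) > 0L) {
    stop("donor(s) present in set B but missing from set C: ",
         paste(missing_pair, collapse = ", "))
  }
  ref <- dplyr::summarise(dplyr::group_by(a, .data$analyte, .data$nominal_conc),
                          ref = mean(.data$resp), n_ref = dplyr::n(),
                          .groups = "drop")
  if (any(ref$n_ref < 3L)) {
    stop("set A needs at least 3 replicates per analyte and level")
  }

  donor_means <- function(x) {
    dplyr::summarise(
      dplyr::group_by(x, .data$analyte, .data$nominal_conc, .data$matrix,
                      .data$donor),
      resp = mean(.data$resp), .groups = "drop")
  }
  bm <- donor_means(b)
  cm <- donor_means(cc)
  er_tbl <- dplyr::inner_join(
    bm, cm,
    by = c("analyte", "nominal_conc", "matrix", "donor"),
    suffix = c("_b", "_c"))
  er_tbl$er <- er_tbl$resp_c / er_tbl$resp_b * 100

  me_src <- if (by == "replicate") b else bm
  pe_src <- if (by == "replicate") cc else cm
  me_tbl <- dplyr::inner_join(me_src, ref, by = c("analyte", "nominal_conc"))
  me_tbl$me <- me_tbl$resp / me_tbl$ref * 100
  pe_tbl <- dplyr::inner_join(pe_src, ref, by = c("analyte", "nominal_conc"))
  pe_tbl$pe <- pe_tbl$resp / pe_tbl$ref * 100

  rsd <- function(x) if (length(x) < 2L) 0 else stats::sd(x) / mean(x) * 100
  me_sum <- dplyr::summarise(
    dplyr::group_by(me_tbl, .data$analyte, .data$nominal_conc, .data$matrix),
    me_mean_deviation = mean(.data$me) - 100, me_rsd = rsd(.data$me),
    n_me = dplyr::n(), .groups = "drop")
  er_sum <- dplyr::summarise(
    dplyr::group_by(er_tbl, .data$analyte, .data$nominal_conc, .data$matrix),
    er_mean = mean(.data$er), er_rsd = rsd(.data$er),
    n_er = dplyr::n(), .groups = "drop")
  pe_sum <- dplyr::summarise(
    dplyr::group_by(pe_tbl, .data$analyte, .data$nominal_conc, .data$matrix),
    pe_mean = mean(.data$pe), pe_rsd = rsd(.data$pe),
    n_pe = dplyr::n(), .groups = "drop")

  out <- dplyr::inner_join(me_sum, er_sum,
                           by = c("analyte", "nominal_conc", "matrix"))
  out <- dplyr::inner_join(out, pe_sum,
                           by = c("analyte", "nominal_conc", "matrix"))
  out$normalized <- normalized
  out <- dplyr::rename(out, level = "nominal_conc", matrix_class = "matrix")
  out <- dplyr::arrange(out, .data$analyte, .data$level, .data$matrix_class)
  if (by == "donor") {
    dv <- dplyr::inner_join(
      dplyr::select(dplyr::mutate(me_tbl, me = .data$me),
                    "analyte", "nominal_conc", "matrix", "donor", "me"),
      dplyr::select(er_tbl, "analyte", "nominal_conc", "matrix", "donor", "er"),
      by = c("analyte", "nominal_conc", "matrix", "donor"))
    dv <- dplyr::inner_join(
      dv,
      dplyr::select(pe_tbl, "analyte", "nominal_conc", "matrix", "donor", "pe"),
      by = c("analyte", "nominal_conc", "matrix", "donor"))
    attr(out, "donor_values") <- dv
  }
  out
}
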