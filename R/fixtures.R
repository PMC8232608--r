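# Packaged reference tables: damage-yield spectra at 21% O2 for six depths of
# a 62-MeV proton track, DSB induction yields and RBE at 21/2/0.1% O2,
# excision-repair outcome probabilities, enzymatic-DSB yields, and the RMF
# parameter sets per oxygen condition. Values are stored exactly as printed
# (3 significant figures) with standard deviations where reported.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "protonRBE", mustWork = FALSE)
  if (!nzchar(p) || !file.exists(p))
    stop("packaged fixture not found: ", file, call. = FALSE)
  p
}

read_fixture <- function(file) {
  p <- fixture_path(file)
  df <- tryCatch(read.delim(p, check.names = FALSE),
                 error = function(e) stop("corrupt fixture ", file, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L) stop("corrupt fixture (empty): ", file, call. = FALSE)
  df
}

#' Load the packaged reference tables
#'
#' Returns all in-package data as printed in the source tables:
#' per-category damage yields at 21% O2 for depths P1 to P6
#' (`damage_yields`), DSB induction yields with RBE at 21/2/0.1% O2 including
#' the cobalt-60 reference (`dsb_yields`; reference LET 2.4 keV/um, yields
#' 8.14/6.85/3.48 per Gy per Gbp), excision-repair outcome probabilities per
#' pathway (`repair_outcomes`), enzymatic-DSB conversion yields with the 6.00
#' per Gy per Gbp reference (`enzymatic_dsb`), the position records with LET
#' (`positions`), and the RMF parameter sets per oxygen condition
#' (`rmf_parameters`).
#'
#' @return Named list of data frames.
#' @examples
#' tables <- load_fixture_tables()
#' subset(tables$dsb_yields, position == "P6" & oxygen_pct == 21)
#' @export
load_fixture_tables <- function() {
  list(
    damage_yields = read_fixture("damage_yields_62mev_21pct.tsv"),
    dsb_yields = read_fixture("dsb_yields_by_oxygen.tsv"),
    repair_outcomes = read_fixture("repair_outcomes.tsv"),
    enzymatic_dsb = read_fixture("enzymatic_dsb_yields.tsv"),
    positions = read_fixture("positions.tsv"),
    rmf_parameters = read_fixture("rmf_parameters.tsv")
  )
}

#' Look up a packaged DSB induction yield
#'
#' @param position Position label (`"P1"`..`"P6"` or `"Co60"`).
#' @param oxygen_pct Oxygen concentration: 21, 2 or 0.1.
#' @param tables Optionally a pre-loaded [load_fixture_tables()] result.
#' @return DSB yield per Gy per Gbp.
#' @export
dsb_yield <- function(position, oxygen_pct, tables = load_fixture_tables()) {
  df <- tables$dsb_yields
  hit <- df$position == position & df$oxygen_pct == oxygen_pct
  if (!any(hit))
    stop("no packaged DSB yield for position '", position, "' at ",
         oxygen_pct, "% O2", call. = FALSE)
  df$dsb_yield[hit][1L]
}

#' Packaged damage spectrum for one position
#'
#' @param position Position label `"P1"`..`"P6"`.
#' @param tables Optionally a pre-loaded [load_fixture_tables()] result.
#' @return A [damage_spectrum()] at 21% O2.
#' @export
fixture_spectrum <- function(position, tables = load_fixture_tables()) {
  df <- tables$damage_yields
  hit <- df$position == position
  if (!any(hit))
    stop("no packaged damage spectrum for position '", position, "'",
         call. = FALSE)
  row <- df[hit, , drop = FALSE][1L, ]
  damage_spectrum(
    setNames(as.numeric(row[.damage_categories]), .damage_categories),
    position = position, oxygen_pct = row$oxygen_pct
  )
}

#' Packaged RMF parameters for one oxygen condition
#'
#' @param oxygen_pct Oxygen concentration: 21, 2 or 0.1.
#' @param f_R Override for the default rejoinable fraction; `NULL` uses the
#'   packaged default (0.99 at 21% and 2% O2, 0.98 at 0.1% O2).
#' @param tables Optionally a pre-loaded [load_fixture_tables()] result.
#' @return An [rmf_parameters()] object with attribute `f_R` and
#'   `f_R_source` (`"default"` or `"user"`).
#' @export
fixture_rmf_parameters <- function(oxygen_pct, f_R = NULL,
                                   tables = load_fixture_tables()) {
  df <- tables$rmf_parameters
  hit <- df$oxygen_pct == oxygen_pct
  if (!any(hit))
    stop("no packaged RMF parameters for ", oxygen_pct, "% O2", call. = FALSE)
  row <- df[hit, , drop = FALSE][1L, ]
  p <- rmf_parameters(theta = row$theta, kappa = row$kappa, j = row$j,
                      nuclear_diameter = row$nuclear_diameter_um,
                      genome_gbp = row$genome_gbp)
  attr(p, "f_R") <- if (is.null(f_R)) row$f_R_default else f_R
  attr(p, "f_R_source") <- if (is.null(f_R)) "default" else "user"
  p
}
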