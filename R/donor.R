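#' Probe substrate with stock-solution composition
#'
#' A probe substrate as prepared for a transport experiment: a concentrated
#' stock solution in one or more solvents, later diluted into medium to the
#' working (donor) concentration. The solvent composition is a named vector of
#' volume fractions which must sum to 1, e.g. `c(DMSO = 1)` for a neat DMSO
#' stock or `c(water = 0.5, DMSO = 0.5)` for a 50:50 stock.
#'
#' @param name substrate identifier.
#' @param transporter_class transport route the substrate probes; one of
#'   `"paracellular"`, `"transcellular"`, `"P-gp"`, `"MRP"`, `"BCRP"`,
#'   `"OCT"`, `"OAT"`.
#' @param stock_concentration stock concentration in mM.
#' @param stock_solvent named numeric vector of solvent volume fractions
#'   summing to 1.
#' @return An object of class `"probe_substrate"`.
#' @examples
#' atenolol <- probe_substrate("atenolol", "paracellular", 50,
#'                             c(water = 0.5, DMSO = 0.5))
#' @export
probe_substrate <- function(name, transporter_class = c("paracellular",
                            "transcellular", "P-gp", "MRP", "BCRP", "OCT", "OAT"),
                            stock_concentration, stock_solvent = c(DMSO = 1)) {
  transporter_class <- match.arg(transporter_class)
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(stock_concentration), length(stock_concentration) == 1L,
            is.numeric(stock_solvent), !is.null(names(stock_solvent)))
  if (!(stock_concentration > 0)) stop("stock_concentration must be > 0")
  if (any(stock_solvent < 0 | stock_solvent > 1))
    stop("solvent fractions must lie in [0, 1]")
  if (abs(sum(stock_solvent) - 1) > 1e-9)
    stop("solvent fractions must sum to 1")
  structure(list(name = name, transporter_class = transporter_class,
                 stock_concentration = stock_concentration,
                 stock_solvent = stock_solvent),
            class = "probe_substrate")
}

#' Donor solution of one or more probe substrates
#'
#' A dosing solution made by diluting each substrate's stock into medium to a
#' common final concentration. The final concentration must not exceed any
#' member's stock concentration.
#'
#' @param substrates a `probe_substrate` or list of them.
#' @param final_concentration working concentration of each substrate in µM
#'   (default 50).
#' @param medium free-text medium tag.
#' @return An object of class `"donor_solution"`.
#' @examples
#' mix <- donor_solution(list(
#'   probe_substrate("atenolol", "paracellular", 50, c(water = 0.5, DMSO = 0.5)),
#'   probe_substrate("propranolol", "transcellular", 50, c(DMSO = 1)),
#'   probe_substrate("fexofenadine", "P-gp", 100, c(DMSO = 1))))
#' solvent_fraction(mix, "DMSO")  # 0.2 (%)
#' @export
donor_solution <- function(substrates, final_concentration = 50,
                           medium = "differentiation medium") {
  if (inherits(substrates, "probe_substrate")) substrates <- list(substrates)
  stopifnot(is.list(substrates), length(substrates) >= 1L,
            all(vapply(substrates, inherits, logical(1), "probe_substrate")),
            is.numeric(final_concentration), length(final_concentration) == 1L)
  if (!(final_concentration > 0)) stop("final_concentration must be > 0")
  for (s in substrates) {
    # stock is mM, final is uM
    if (final_concentration > s$stock_concentration * 1000)
      stop(sprintf("invalid dilution: final %g uM exceeds %s stock %g mM",
                   final_concentration, s$name, s$stock_concentration))
  }
  structure(list(substrates = substrates,
                 final_concentration = final_concentration,
                 medium = as.character(medium)),
            class = "donor_solution")
}

#' Residual solvent fraction of a donor solution
#'
#' Volume percentage of a named solvent carried into the donor solution from
#' the substrate stocks. Each substrate diluted from `stock` (mM) to `final`
#' (µM) contributes `final/stock` of its stock volume, of which the named
#' solvent makes up its stock volume fraction. Contributions are additive over
#' substrates; a solvent absent from every stock contributes zero.
#'
#' @param donor a [donor_solution()].
#' @param solvent_name solvent to account for, e.g. `"DMSO"`.
#' @return Volume fraction in percent.
#' @export
solvent_fraction <- function(donor, solvent_name) {
  stopifnot(inherits(donor, "donor_solution"),
            is.character(solvent_name), length(solvent_name) == 1L)
  contrib <- vapply(donor$substrates, function(s) {
    dilution <- donor$final_concentration / (s$stock_concentration * 1000)
    frac <- s$stock_solvent[solvent_name]
    if (is.na(frac)) frac <- 0
    dilution * unname(frac)
  }, numeric(1))
  100 * sum(contrib)
}
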