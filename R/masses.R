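#' Amino-acid residue masses
#'
#' Monoisotopic and average residue (i.e. dehydrated) masses for the 20
#' standard amino acids, in daltons.
#'
#' @return A data frame with columns `residue` (one-letter code), `mono`
#'   and `avg` (Da).
#' @export
amino_acid_masses <- function() {
  .aa_mass_table
}

.aa_mass_table <- data.frame(
  residue = c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N",
              "D", "Q", "K", "E", "M", "H", "F", "R", "Y", "W"),
  mono = c(57.02146, 71.03711, 87.03203, 97.05276, 99.06841,
           101.04768, 103.00919, 113.08406, 113.08406, 114.04293,
           115.02694, 128.05858, 128.09496, 129.04259, 131.04049,
           137.05891, 147.06841, 156.10111, 163.06333, 186.07931),
  avg = c(57.0519, 71.0788, 87.0782, 97.1167, 99.1326,
          101.1051, 103.1388, 113.1594, 113.1594, 114.1038,
          115.0886, 128.1307, 128.1741, 129.1155, 131.1926,
          137.1411, 147.1766, 156.1875, 163.1760, 186.2132),
  stringsAsFactors = FALSE
)

# mass constants (Da)
.mass_water_mono <- 18.010565
.mass_water_avg  <- 18.01528
.mass_proton     <- 1.007276

#' Physical mass constants used throughout
#'
#' @return Named numeric vector with `water_mono`, `water_avg` and
#'   `proton` masses in Da.
#' @export
mass_constants <- function() {
  c(water_mono = .mass_water_mono,
    water_avg  = .mass_water_avg,
    proton     = .mass_proton)
}

#' Define a chemical crosslinker
#'
#' A crosslinker is described by the residues it reacts with, the mass it
#' adds when both ends react (bridge), the mass added when one end
#' hydrolyzes (dead-end), its spacer arm length and the maximum
#' site-to-site distance regarded as productive for crosslinking.
#'
#' For hydrolyzable NHS esters the dead-end mass exceeds the bridge mass
#' by one water. `max_site_distance` is the distance bound used for
#' structure validation and pose filtering; for BS3 the conventional
#' C-beta bound is 21.3 A (spacer 11.4 A plus two lysine side chains).
#'
#' @param name Character label.
#' @param reactive_sites Character vector of one-letter residue codes the
#'   linker reacts with.
#' @param bridge_mass_mono,bridge_mass_avg Mass added by an intact bridge
#'   (Da).
#' @param deadend_mass_mono,deadend_mass_avg Mass added by a hydrolyzed
#'   single-ended product (Da).
#' @param spacer_length Spacer arm length (A).
#' @param max_site_distance Maximum productive site-site distance (A).
#' @param nterm_reactive Logical; is the protein N-terminal alpha-amine a
#'   reactive site? Off by default.
#' @param excluded_sites Integer vector of residue positions never treated
#'   as reactive (e.g. metal-coordinated cysteines for maleimides).
#' @return An object of class `crosslinker_spec`.
#' @export
crosslinker_spec <- function(name, reactive_sites,
                             bridge_mass_mono, bridge_mass_avg = bridge_mass_mono,
                             deadend_mass_mono = NA_real_,
                             deadend_mass_avg = NA_real_,
                             spacer_length, max_site_distance = spacer_length + 10,
                             nterm_reactive = FALSE,
                             excluded_sites = integer(0)) {
  stopifnot(spacer_length > 0, max_site_distance >= spacer_length)
  if (!is.na(deadend_mass_mono) && bridge_mass_mono >= deadend_mass_mono)
    stop("bridge mass must be below dead-end mass for a hydrolyzable linker")
  structure(list(
    name = name,
    reactive_sites = reactive_sites,
    bridge_mass_mono = bridge_mass_mono,
    bridge_mass_avg = bridge_mass_avg,
    deadend_mass_mono = deadend_mass_mono,
    deadend_mass_avg = deadend_mass_avg,
    spacer_length = spacer_length,
    max_site_distance = max_site_distance,
    nterm_reactive = nterm_reactive,
    excluded_sites = as.integer(excluded_sites)
  ), class = "crosslinker_spec")
}

#' Built-in crosslinker definitions
#'
#' `"BS3"`: bis(sulfosuccinimidyl) suberate, amine-reactive, 11.4 A
#' spacer, bridge +138.0681 Da, hydrolyzed dead-end +156.0786 Da,
#' productive C-beta limit 21.3 A. `"BMOE"` and `"BMPEG2"`: bifunctional
#' maleimides for cysteines with 8 A and 14.7 A spacer arms.
#'
#' @param name One of `"BS3"`, `"BMOE"`, `"BMPEG2"`.
#' @param ... Overrides passed to [crosslinker_spec()].
#' @return A `crosslinker_spec`.
#' @export
crosslinker <- function(name = c("BS3", "BMOE", "BMPEG2"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    BS3 = list(name = "BS3", reactive_sites = "K",
               bridge_mass_mono = 138.06808, bridge_mass_avg = 138.1638,
               deadend_mass_mono = 156.07864, deadend_mass_avg = 156.1791,
               spacer_length = 11.4, max_site_distance = 21.3),
    BMOE = list(name = "BMOE", reactive_sites = "C",
                bridge_mass_mono = 220.04840, bridge_mass_avg = 220.18,
                spacer_length = 8, max_site_distance = 18),
    BMPEG2 = list(name = "BMPEG2", reactive_sites = "C",
                  bridge_mass_mono = 308.10083, bridge_mass_avg = 308.29,
                  spacer_length = 14.7, max_site_distance = 24.7))
  override <- list(...)
  args[names(override)] <- override
  do.call(crosslinker_spec, args)
}

#' @export
print.crosslinker_spec <- function(x, ...) {
  cat(sprintf("<crosslinker %s>  sites: %s  bridge: %.4f Da  spacer: %.1f A  max dist: %.1f A\n",
              x$name, paste(x$reactive_sites, collapse = ""),
              x$bridge_mass_mono, x$spacer_length, x$max_site_distance))
  invisible(x)
}
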