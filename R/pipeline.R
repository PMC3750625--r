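#' Assemble a pipeline configuration
#'
#' Collects every setting of the end-to-end run in one validated record;
#' all values are echoed into the run report so each choice is explicit.
#'
#' Inputs may be file paths (FASTA / PDB / two-column peak lists /
#' restraint TSV) or in-memory objects. When peak lists are absent and
#' `restraints` is supplied, the mass-spectrometry stages are skipped and
#' the modelling stages run directly (documented bypass).
#'
#' @param sequence Protein sequence string or FASTA path.
#' @param structure [chain_model()] or PDB path.
#' @param chain Chain to read from a PDB path.
#' @param crosslinked_peaks,control_peaks Peak-list data frames or paths
#'   (optional).
#' @param restraints List of [restraint()]s or restraint TSV path
#'   (optional; required if peak lists are absent).
#' @param protease,max_missed Digestion settings.
#' @param xl A [crosslinker_spec()] or built-in name.
#' @param tolerance,tol_unit,charges Peak matching settings.
#' @param numbering_offset Added to MS/construct site numbers to obtain
#'   structure residue numbers.
#' @param spacing,angle_step,keep,refine_top Docking settings.
#' @param outdir Optional output directory for stage artifacts.
#' @param seed Integer seed echoed into the report (the docking sweep
#'   itself is deterministic).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sequence = NULL, structure = NULL, chain = "A",
                            crosslinked_peaks = NULL, control_peaks = NULL,
                            restraints = NULL,
                            protease = "trypsin", max_missed = 2,
                            xl = "BS3", tolerance = 50, tol_unit = "ppm",
                            charges = 1L, numbering_offset = 0L,
                            spacing = 1.5, angle_step = 30, keep = 2000,
                            refine_top = 10, outdir = NULL, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @return Character vector of problems; empty when runnable.
#' @export
validate_config <- function(config) {
  p <- character(0)
  say <- function(...) p <<- c(p, sprintf(...))
  if (is.null(config$structure)) say("structure: missing")
  else if (is.character(config$structure) && !file.exists(config$structure))
    say("structure: file '%s' does not exist", config$structure)
  has_peaks <- !is.null(config$crosslinked_peaks)
  if (has_peaks) {
    if (is.null(config$sequence)) say("sequence: required when peak lists are given")
    if (is.null(config$control_peaks)) say("control_peaks: missing")
    for (f in c("crosslinked_peaks", "control_peaks")) {
      v <- config[[f]]
      if (is.character(v) && !file.exists(v))
        say("%s: file '%s' does not exist", f, v)
    }
  } else if (is.null(config$restraints)) {
    say("restraints: required when no peak lists are given")
  }
  if (is.character(config$restraints) && !file.exists(config$restraints))
    say("restraints: file '%s' does not exist", config$restraints)
  if (!is.null(config$tolerance) && config$tolerance <= 0)
    say("tolerance: must be > 0")
  if (!config$protease %in% c("trypsin", "chymotrypsin"))
    say("protease: unknown '%s'", config$protease)
  if (config$spacing <= 0) say("spacing: must be > 0")
  if (config$keep < 1) say("keep: must be >= 1")
  p
}

#' Run the crosslink-to-dimer pipeline end to end
#'
#' Stages: digest, enumerate crosslinked products, match against the
#' crosslinked peak list, subtract the control list, classify site pairs
#' against the monomer, derive intermolecular distance restraints, dock,
#' filter, refine, select, and characterize the interface and
#' orientation. When the configuration supplies restraints directly and
#' no peak lists, the MS stages are skipped.
#'
#' The run report reproduces the two summary tables of a crosslink-MS
#' dimer study: a looplink table (peptides, linked sites, within-monomer
#' distances) and an intermolecular table (sites, distances on the
#' selected dimer model).
#'
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_report`: list with `config` (echo),
#'   `log` (stage record counts), `matches`, `classified`,
#'   `looplink_table`, `interlink_table`, `fit` (the [fit_dimer()]
#'   object), `status` (`"ok"` or `"no-compatible-pose"`).
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid config:\n  ", paste(problems, collapse = "\n  "))
  log <- list()
  stage <- function(name, value) {
    log[[name]] <<- value
    message(sprintf("[%s] %s", name, value))
  }

  xl <- if (inherits(config$xl, "crosslinker_spec")) config$xl
        else crosslinker(config$xl)
  monomer <- if (inherits(config$structure, "chain_model")) config$structure
             else edit_mse_to_met(read_chain(config$structure, config$chain))
  off <- config$numbering_offset

  matches <- NULL; classified <- NULL; looplink_table <- NULL
  restraints <- config$restraints
  if (is.character(restraints)) restraints <- read_restraints(restraints)

  if (!is.null(config$crosslinked_peaks)) {
    seq_str <- config$sequence
    seq_off <- 1L
    if (is.character(seq_str) && file.exists(seq_str)) {
      fa <- bio3d::read.fasta(seq_str)
      seq_str <- paste(fa$ali[1, ], collapse = "")
    }
    peps <- digest(seq_str, config$protease, config$max_missed,
                   offset = seq_off)
    stage("digest", sprintf("%d peptides", nrow(peps)))
    prods <- enumerate_products(peps, xl, protease = config$protease)
    stage("enumerate", sprintf("%d candidate products", nrow(prods)))
    xpk <- config$crosslinked_peaks
    if (is.character(xpk)) xpk <- read_peaklist(xpk)
    cpk <- config$control_peaks
    if (is.character(cpk)) cpk <- read_peaklist(cpk)
    matches <- match_peaks(prods, xpk, config$tolerance, config$tol_unit,
                           charges = config$charges)
    stage("match", sprintf("%d matches", nrow(matches)))
    matches <- differential_products(matches, cpk, config$tolerance,
                                     config$tol_unit)
    stage("differential", sprintf("%d differential matches", nrow(matches)))
    linked <- matches[matches$kind %in% c("looplink", "interlink"), ,
                      drop = FALSE]
    linked <- linked[!duplicated(linked[, c("kind", "site1", "site2")]), ,
                     drop = FALSE]
    if (nrow(linked)) {
      pairs <- data.frame(site1 = linked$site1 + off,
                          site2 = linked$site2 + off,
                          from_dimer = linked$kind == "interlink")
      classified <- cbind(kind = linked$kind, pep1 = linked$pep1,
                          pep2 = linked$pep2,
                          classify_crosslinks(pairs, monomer, xl))
      stage("classify", sprintf("%d unique site pairs", nrow(classified)))
      lp <- classified[classified$kind == "looplink", , drop = FALSE]
      looplink_table <- lp[, c("pep1", "site1", "site2", "distance")]
      if (is.null(restraints)) {
        # one restraint per distinct product mass: site assignments that
        # share a peak are indistinguishable at the MS1 level and enter
        # as alternatives of a single ambiguous restraint
        inter <- matches[matches$kind == "interlink", , drop = FALSE]
        restraints <- list()
        for (mkey in unique(round(inter$mass_mono, 4))) {
          rows <- inter[round(inter$mass_mono, 4) == mkey, , drop = FALSE]
          alts <- unique(data.frame(a = rows$site1 + off,
                                    b = rows$site2 + off))
          lab <- paste(unique(paste0(alts$a, "-", alts$b)), collapse = "/")
          restraints[[length(restraints) + 1L]] <-
            restraint(max_distance = xl$max_site_distance, origin = lab,
                      alternatives = alts)
        }
        # drop restraints whose alternative set duplicates another's
        key <- vapply(restraints, function(r)
          paste(sort(paste0(r$alternatives$a, "-", r$alternatives$b)),
                collapse = ","), character(1))
        restraints <- restraints[!duplicated(key)]
      }
    }
  }
  if (!length(restraints %||% list()))
    stop("no intermolecular restraints derived or supplied")
  stage("restraints", sprintf("%d restraints", length(restraints)))

  fit <- fit_dimer(monomer, monomer, restraints,
                   spacing = config$spacing, angle_step = config$angle_step,
                   keep = config$keep, refine_top = config$refine_top)
  stage("dock-filter-select",
        sprintf("%d/%d poses survive; status %s", fit$filter_report$n_out,
                fit$filter_report$n_in, fit$status))

  interlink_table <- NULL
  if (fit$status == "ok" && !is.null(fit$restraint_distances)) {
    interlink_table <- fit$restraint_distances
  }
  report <- structure(list(config = config, log = log, matches = matches,
                           classified = classified,
                           looplink_table = looplink_table,
                           interlink_table = interlink_table,
                           fit = fit, status = fit$status),
                      class = "pipeline_report")
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$matches))
    write_tsv(report$matches, file.path(outdir, "matches.tsv"))
  if (!is.null(report$classified))
    write_tsv(report$classified, file.path(outdir, "classified.tsv"))
  if (!is.null(report$looplink_table))
    write_tsv(report$looplink_table, file.path(outdir, "looplink_table.tsv"))
  if (!is.null(report$interlink_table))
    write_tsv(report$interlink_table, file.path(outdir, "interlink_table.tsv"))
  if (report$status == "ok") {
    write_structure(report$fit$complex, file.path(outdir, "selected_dimer.pdb"))
    write_tsv(report$fit$poses$poses, file.path(outdir, "poses.tsv"))
  }
  invisible(outdir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Crosslink-guided dimer pipeline report\n")
  for (nm in names(x$log)) cat(sprintf("  %-18s %s\n", nm, x$log[[nm]]))
  if (!is.null(x$looplink_table)) {
    cat("\nLooplinks (within-monomer distances, A):\n")
    print(x$looplink_table, row.names = FALSE)
  }
  if (!is.null(x$interlink_table)) {
    cat("\nIntermolecular restraints on the selected model (A):\n")
    print(x$interlink_table, row.names = FALSE)
  }
  if (x$status == "ok") {
    print(x$fit)
  } else cat("\nNO restraint-compatible pose found.\n")
  invisible(x)
}
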