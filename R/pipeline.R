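#' Assemble an analysis configuration
#'
#' Collects the inputs for [run_pipeline()].  Each stage input may be given
#' as an in-memory object or as a file path (orbital listings in the qcf
#' dialect, densities as cube files, the structure as a SMILES string or
#' file).  Only a frontier source (spectrum or explicit frontier energies)
#' is mandatory; stages without inputs are skipped with a notice.
#'
#' @param spectrum an [orbital_spectrum], or a path to a qcf orbital file.
#' @param frontier a [frontier_energies]; overrides `spectrum` when given.
#' @param conformers optional list of [qm_result]s; the lowest-energy one
#'   (after a minimum check when frequencies are present) becomes the
#'   reported species.
#' @param energies optional list `(e_n, e_nm1, e_np1)` of total energies in
#'   hartree for the Koopmans-compliance diagnostics and Delta-SCF mode.
#' @param charge_triplet optional list `(q_n, q_nm1, q_np1)` of
#'   [charge_set]s.
#' @param grid_triplet optional list `(rho_n, rho_nm1, rho_np1)` of
#'   [volumetric_grid]s or cube-file paths.
#' @param smiles optional SMILES string or file.
#' @param bioactivity optional named list of externally supplied scores
#'   (any subset of gpcr, ion_channel, kinase, nuclear_receptor, protease,
#'   enzyme).
#' @param milogp_input,volume_input optional externally supplied
#'   Molinspiration values.
#' @param ia_mode `"vertical"` (Koopmans, default) or `"delta_scf"`
#'   (requires `energies`).
#' @param top_k how many top sites to report per condensed-Fukui channel.
#' @param label species label for the report.
#' @param seed recorded in the report provenance.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(spectrum = NULL, frontier = NULL,
                            conformers = NULL, energies = NULL,
                            charge_triplet = NULL, grid_triplet = NULL,
                            smiles = NULL, bioactivity = NULL,
                            milogp_input = NULL, volume_input = NULL,
                            ia_mode = c("vertical", "delta_scf"),
                            top_k = 5L, label = "species", seed = NA_integer_) {
  ia_mode <- match.arg(ia_mode)
  if (is.character(spectrum)) spectrum <- parse_orbital_energies(spectrum)
  if (!is.null(grid_triplet))
    grid_triplet <- lapply(grid_triplet, function(g)
      if (is.character(g)) read_cube(g) else g)
  structure(list(spectrum = spectrum, frontier = frontier,
                 conformers = conformers, energies = energies,
                 charge_triplet = charge_triplet, grid_triplet = grid_triplet,
                 smiles = smiles, bioactivity = bioactivity,
                 milogp_input = milogp_input, volume_input = volume_input,
                 ia_mode = ia_mode, top_k = as.integer(top_k),
                 label = label, seed = seed),
            class = "analysis_config")
}

#' Run the full reactivity / drug-likeness analysis
#'
#' Orchestrates the stages on whatever inputs the configuration provides:
#' conformer selection and minimum verification, frontier extraction,
#' global CDFT descriptors and the gap-based absorption wavelength,
#' Koopmans-compliance diagnostics, condensed and grid Fukui descriptors,
#' the drug-likeness property block, and bioactivity-score classification.
#' A stage whose inputs are absent is skipped and marked in `$skipped`.
#' Stages are isolated: corrupt inputs fail only their own block, recorded
#' under `$errors` with the stage name, and the remaining blocks are still
#' computed (with `strict = TRUE` the first stage error aborts the run
#' instead).  A missing frontier source is always a hard error: nothing
#' downstream is defined without it.
#'
#' @param config an [analysis_config], or a [fixture_bundle] (its fields
#'   are mapped onto a configuration).
#' @param strict abort on the first stage error instead of recording it.
#' @return An object of class `cdft_report`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(taltobulin_fixture())
#' rep$global$chi
#' }
#' @export
run_pipeline <- function(config, strict = FALSE) {
  if (inherits(config, "fixture_bundle"))
    config <- analysis_config(
      spectrum = config$spectrum, conformers = config$conformers,
      energies = config$energies,
      charge_triplet = config$charge_triplet,
      grid_triplet = config$grid_triplet, smiles = config$smiles,
      bioactivity = config$bioactivity,
      milogp_input = config$milogp_input,
      volume_input = config$volume_input,
      label = "taltobulin", seed = config$seed)
  stopifnot(inherits(config, "analysis_config"))
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      msg <- sprintf("stage '%s': %s", name, conditionMessage(e))
      if (strict) stop(msg, call. = FALSE)
      errors[[name]] <<- msg
      NULL
    })
  }
  skipped <- character(0)
  report <- list(label = config$label)

  # conformer bookkeeping
  if (!is.null(config$conformers)) {
    best <- stage("conformers", {
      sel <- select_lowest_conformer(config$conformers)
      if (!is.null(sel$frequencies) && !check_minimum(sel$frequencies))
        stop("selected conformer is not a true minimum")
      sel
    })
    report$species <- best$label
    report$total_energy <- best$total_energy
  } else skipped <- c(skipped, "conformers")

  # frontier source and global descriptors: the pipeline's core, always fatal
  hard <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  frontier <- config$frontier
  if (is.null(frontier) && !is.null(config$spectrum))
    frontier <- hard("frontier", frontier_from_spectrum(config$spectrum))
  if (is.null(frontier))
    stop("stage 'frontier': no frontier source (spectrum or frontier ",
         "energies) in the configuration", call. = FALSE)
  report$frontier <- frontier

  report$ia_mode <- config$ia_mode
  report$global <- hard("global", {
    if (config$ia_mode == "delta_scf") {
      e <- config$energies
      if (is.null(e))
        stop("delta_scf mode needs the N, N-1, N+1 total energies")
      global_descriptors(finite_difference_ia(e$e_n, e$e_nm1, e$e_np1))
    } else global_descriptors(frontier)
  })

  # Koopmans-compliance diagnostics
  if (!is.null(config$energies)) {
    report$kid <- stage("kid", with(config$energies,
      kid_diagnostics(e_n, e_nm1, e_np1, frontier)))
  } else skipped <- c(skipped, "kid")

  # condensed Fukui
  if (!is.null(config$charge_triplet)) {
    report$condensed_fukui <- stage("condensed_fukui", {
      cf <- with(config$charge_triplet, condensed_fukui(q_n, q_nm1, q_np1))
      k <- min(config$top_k, length(cf$f_minus))
      list(fukui = cf,
           sums = c(f_minus = sum(cf$f_minus), f_plus = sum(cf$f_plus),
                    dual = sum(cf$dual)),
           top_electrophilic = rank_sites(cf, "f_minus", k),
           top_nucleophilic = rank_sites(cf, "f_plus", k))
    })
  } else skipped <- c(skipped, "condensed_fukui")

  # grid Fukui
  if (!is.null(config$grid_triplet)) {
    report$grid_fukui <- stage("grid_fukui", {
      fk <- with(config$grid_triplet, grid_fukui(rho_n, rho_nm1, rho_np1))
      list(fields = fk,
           integrals = c(f_minus = grid_integral(fk$f_minus),
                         f_plus = grid_integral(fk$f_plus),
                         dual = grid_integral(fk$dual)))
    })
  } else skipped <- c(skipped, "grid_fukui")

  # drug-likeness
  if (!is.null(config$smiles)) {
    report$drug_profile <- stage("druglikeness",
      drug_profile(config$smiles, milogp_input = config$milogp_input,
                   volume_input = config$volume_input))
  } else skipped <- c(skipped, "druglikeness")

  # bioactivity interpretation
  if (!is.null(config$bioactivity)) {
    report$bioactivity <- stage("bioactivity", {
      sc <- config$bioactivity
      data.frame(target = names(sc), score = unlist(sc, use.names = FALSE),
                 category = classify_bioactivity(unlist(sc,
                                                        use.names = FALSE)),
                 row.names = NULL)
    })
  } else skipped <- c(skipped, "bioactivity")

  report$skipped <- skipped
  report$errors <- errors
  report$provenance <- list(
    package = "cdftkit",
    version = as.character(utils::packageVersion("cdftkit")),
    ia_mode = config$ia_mode, seed = config$seed)
  structure(report, class = "cdft_report")
}

#' @export
print.cdft_report <- function(x, ...) {
  cat(sprintf("== CDFT analysis report: %s ==\n", x$label))
  if (!is.null(x$total_energy))
    cat(sprintf("total energy        %12.3f au  (%s)\n", x$total_energy,
                x$species))
  cat(sprintf("HOMO / LUMO         %8.3f / %.3f eV\n",
              x$frontier$e_homo, x$frontier$e_lumo))
  print(x$global)
  if (!is.null(x$kid)) print(x$kid)
  if (!is.null(x$condensed_fukui)) {
    s <- x$condensed_fukui$sums
    cat(sprintf("condensed Fukui sums: f- %.4f, f+ %.4f, dual %.4f\n",
                s[1], s[2], s[3]))
  }
  if (!is.null(x$grid_fukui)) {
    s <- x$grid_fukui$integrals
    cat(sprintf("grid Fukui integrals: f- %.4f, f+ %.4f, dual %.4f\n",
                s[1], s[2], s[3]))
  }
  if (!is.null(x$drug_profile)) print(x$drug_profile)
  if (!is.null(x$bioactivity)) {
    cat("bioactivity:\n")
    print(x$bioactivity)
  }
  if (length(x$skipped))
    cat("skipped stages:", paste(x$skipped, collapse = ", "), "\n")
  if (length(x$errors))
    cat("failed stages:\n ", paste(unlist(x$errors), collapse = "\n  "), "\n")
  invisible(x)
}

# Flatten the report's scalar quantities, unrounded.
.report_scalars <- function(r) {
  out <- c(list(label = r$label),
           if (!is.null(r$total_energy)) list(total_energy_au =
                                                r$total_energy),
           list(e_homo_ev = r$frontier$e_homo, e_lumo_ev = r$frontier$e_lumo),
           r$global[c("i_vertical", "a_vertical", "chi", "mu", "eta",
                      "softness", "omega", "omega_minus", "omega_plus",
                      "net_electrophilicity", "lambda_max")])
  if (!is.null(r$kid)) out <- c(out, list(j_i = r$kid$j_i, j_a = r$kid$j_a,
                                          j_hl = r$kid$j_hl))
  if (!is.null(r$drug_profile)) {
    p <- r$drug_profile
    out <- c(out, list(mw = p$mw, n_atoms = p$n_atoms, n_on = p$n_on,
                       n_ohnh = p$n_ohnh, n_rotb = p$n_rotb, tpsa = p$tpsa,
                       logp = p$logp, nviol = p$nviol))
    if (!is.null(p$milogp_input)) out$milogp <- p$milogp_input
    if (!is.null(p$volume_input)) out$volume <- p$volume_input
  }
  out
}

#' Render an analysis report
#'
#' `"json"` is lossless for the report's numeric content (unrounded values;
#' re-parsing yields an equal set of quantities).  `"csv"` flattens the
#' scalar fields to a two-column table.  `"markdown"` presents the blocks
#' in the reference order with reporting precision: eV quantities to 3
#' decimals, the wavelength to the nearest nm, MW/TPSA to 2 decimals.
#'
#' @param r a `cdft_report` from [run_pipeline()].
#' @param format `"json"`, `"csv"` or `"markdown"`.
#' @return A character vector (one element per line for csv/markdown; one
#'   JSON string for json).
#' @export
render_report <- function(r, format = c("json", "csv", "markdown")) {
  stopifnot(inherits(r, "cdft_report"))
  if (length(format) == 1L && !format %in% c("json", "csv", "markdown"))
    stop("unknown report format: ", format, call. = FALSE)
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(
      scalars = .report_scalars(r),
      condensed_fukui = if (!is.null(r$condensed_fukui))
        as.data.frame(r$condensed_fukui$fukui),
      fukui_sums = if (!is.null(r$condensed_fukui))
        as.list(r$condensed_fukui$sums),
      grid_integrals = if (!is.null(r$grid_fukui))
        as.list(r$grid_fukui$integrals),
      bioactivity = r$bioactivity,
      skipped = r$skipped,
      errors = r$errors,
      provenance = r$provenance)
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                         digits = NA, null = "null")))
  }
  if (format == "csv") {
    sc <- .report_scalars(r)
    vals <- vapply(sc, function(v)
      if (is.numeric(v)) sprintf("%.12g", v) else as.character(v),
      character(1))
    return(c("quantity,value", paste(names(sc), vals, sep = ",")))
  }
  # markdown, reference presentation order
  fmt <- function(x, d) formatC(round(x, d), format = "f", digits = d)
  g <- r$global
  out <- c(sprintf("# CDFT analysis: %s", r$label), "",
           "| quantity | value |", "|---|---|")
  if (!is.null(r$total_energy))
    out <- c(out, sprintf("| total energy (au) | %.3f |", r$total_energy))
  out <- c(out,
    sprintf("| HOMO (eV) | %s |", fmt(r$frontier$e_homo, 3)),
    sprintf("| LUMO (eV) | %s |", fmt(r$frontier$e_lumo, 3)),
    sprintf("| lambda_max (nm) | %.0f |", g$lambda_max),
    sprintf("| chi (eV) | %s |", fmt(g$chi, 3)),
    sprintf("| eta (eV) | %s |", fmt(g$eta, 3)),
    sprintf("| omega (eV) | %s |", fmt(g$omega, 3)),
    sprintf("| omega- (eV) | %s |", fmt(g$omega_minus, 3)),
    sprintf("| omega+ (eV) | %s |", fmt(g$omega_plus, 3)),
    sprintf("| net electrophilicity (eV) | %s |",
            fmt(g$net_electrophilicity, 3)))
  if (!is.null(r$drug_profile)) {
    p <- r$drug_profile
    out <- c(out, "", "## Drug-likeness", "", "| property | value |",
             "|---|---|",
             if (!is.null(p$milogp_input))
               sprintf("| miLogP (supplied) | %.2f |", p$milogp_input),
             sprintf("| logP (stand-in) | %s |", fmt(p$logp, 2)),
             sprintf("| TPSA (A^2) | %s |", fmt(p$tpsa, 2)),
             sprintf("| nAtoms | %d |", p$n_atoms),
             sprintf("| nON | %d |", p$n_on),
             sprintf("| nOHNH | %d |", p$n_ohnh),
             sprintf("| nviol | %d |", p$nviol),
             sprintf("| nrotb | %d |", p$n_rotb),
             if (!is.null(p$volume_input))
               sprintf("| volume (supplied, A^3) | %.2f |", p$volume_input),
             sprintf("| MW (Da) | %s |", fmt(p$mw, 2)))
  }
  if (!is.null(r$bioactivity)) {
    out <- c(out, "", "## Bioactivity", "", "| target | score | category |",
             "|---|---|---|",
             sprintf("| %s | %.2f | %s |", r$bioactivity$target,
                     r$bioactivity$score, r$bioactivity$category))
  }
  out
}
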