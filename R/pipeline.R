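# End-to-end orchestration: a single validated config drives the encode,
# entropy, MI, biophysical-profile, potential, breakdown, contact and
# comparison stages in dependency order, writing CSV outputs and a JSON
# manifest with per-output hashes.

.PIPELINE_STAGES <- c("encode", "entropy", "mi", "biophys", "potential",
                      "breakdown", "contacts", "compare")

#' Validate a pipeline run configuration
#'
#' A config is a named list (or a YAML/JSON file path) with:
#' \describe{
#'   \item{tcr_fasta / mhc_fasta}{input FASTA paths (with
#'     \code{tcr_family}, \code{mhc_family} labels)}
#'   \item{region_definitions}{path to a family -> region -> positions
#'     config}
#'   \item{stages}{subset of encode, entropy, mi, biophys, potential,
#'     breakdown, contacts, compare}
#'   \item{seed}{mandatory when any stochastic stage (entropy, mi,
#'     compare) is requested}
#'   \item{n_subsample, n_repetitions}{entropy/MI subsampling parameters}
#'   \item{property}{"charge" or "hydropathy" for the biophys stage}
#'   \item{structures}{for the contacts stage: list of
#'     \code{list(pdb=, annotation=)} paths}
#'   \item{n_perm}{permutations for the compare stage}
#'   \item{output_dir}{directory for outputs}
#' }
#'
#' @param config Named list or path to a YAML/JSON file.
#' @return The validated config (classed \code{run_config}).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  fail <- function(...) {
    stop(structure(class = c("config_error", "error", "condition"),
                   list(message = paste0(...), call = sys.call(-1))))
  }
  if (is.null(config$stages)) config$stages <- .PIPELINE_STAGES[1:5]
  bad <- setdiff(config$stages, .PIPELINE_STAGES)
  if (length(bad) > 0L) fail("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(config$output_dir)) fail("output_dir is required")
  for (p in c("tcr_fasta", "mhc_fasta", "region_definitions")) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]])) {
      fail("configured file does not exist: ", p, " = ", config[[p]])
    }
  }
  if (any(c("entropy", "mi", "compare") %in% config$stages) &&
      is.null(config$seed)) {
    fail("seed is mandatory for stochastic stages")
  }
  needs_seq <- c("encode", "entropy", "mi", "biophys", "potential",
                 "breakdown")
  if (any(needs_seq %in% config$stages)) {
    if (is.null(config$tcr_fasta) || is.null(config$region_definitions)) {
      fail("sequence stages require tcr_fasta and region_definitions")
    }
  }
  if ("contacts" %in% config$stages && is.null(config$structures)) {
    fail("contacts stage requires structures")
  }
  if (is.null(config$n_repetitions)) config$n_repetitions <- 1000L
  if (is.null(config$n_perm)) config$n_perm <- 10000L
  if (is.null(config$property)) config$property <- "charge"
  if (is.null(config$tcr_family)) config$tcr_family <- "TRBV"
  if (is.null(config$mhc_family)) config$mhc_family <- "HLA-I"
  class(config) <- c("run_config", "list")
  config
}

.stage_error <- function(stage, e) {
  stop(structure(class = c("stage_error", "error", "condition"),
                 list(message = paste0("stage '", stage, "' failed: ",
                                       conditionMessage(e)),
                      call = NULL, stage = stage)))
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order, writes each stage's
#' CSV outputs under \code{output_dir} and returns (and writes) a manifest
#' recording, per stage, the parameters used and the md5 hash of every
#' output file. With the same config and seed, deterministic stages
#' reproduce their hashes. A stage failure halts the run with a
#' stage-scoped condition; the partial manifest is still written.
#'
#' @param config A \code{run_config}, raw list, or config file path (see
#'   \code{\link{validate_config}}).
#' @return Invisibly, the manifest (also written to
#'   \code{output_dir/manifest.json}).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  out_path <- function(name) file.path(config$output_dir, name)
  note <- function(stage, params, files) {
    manifest[[stage]] <<- list(
      stage = stage, parameters = params,
      outputs = lapply(files, function(f) {
        list(path = f, md5 = unname(tools::md5sum(f)))
      }))
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, out_path("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  on.exit(write_manifest())

  state <- new.env()
  run_stage <- function(stage, f) {
    if (!stage %in% config$stages) return(invisible(NULL))
    tryCatch(f(), error = function(e) .stage_error(stage, e))
  }
  needs_seq <- any(c("encode", "entropy", "mi", "biophys", "potential",
                     "breakdown") %in% config$stages)
  if (needs_seq) {
    defs <- read_region_definitions(config$region_definitions)
    load_side <- function(fasta, family) {
      rec <- read_family_fasta(fasta, family = family)
      if (is.null(defs[[family]])) {
        stop("no region definition for family ", family)
      }
      rec <- extract_family_regions(rec, defs[[family]])
      filter_productive_unique(rec)
    }
    state$tcr <- load_side(config$tcr_fasta, config$tcr_family)
    if (!is.null(config$mhc_fasta)) {
      state$mhc <- load_side(config$mhc_fasta, config$mhc_family)
    }
    state$tcr_mat <- encode_repertoire(state$tcr)
    if (!is.null(state$mhc)) state$mhc_mat <- encode_repertoire(state$mhc)
  }

  run_stage("encode", function() {
    files <- write_aims_matrix(state$tcr_mat, out_path("tcr_encoded.csv"))
    if (!is.null(state$mhc_mat)) {
      files <- c(files, write_aims_matrix(state$mhc_mat,
                                          out_path("mhc_encoded.csv")))
    }
    note("encode", list(pad_mode = state$tcr_mat$pad_mode), as.list(files))
  })

  run_stage("entropy", function() {
    ns <- if (!is.null(config$n_subsample)) config$n_subsample
          else nrow(state$tcr_mat$codes)
    prof <- subsampled_entropy_profile(state$tcr_mat, n_subsample = ns,
                                      n_repetitions = config$n_repetitions,
                                      seed = config$seed)
    f <- out_path("entropy_profile.csv")
    utils::write.csv(prof, f, row.names = FALSE)
    note("entropy", list(n_subsample = ns,
                         n_repetitions = config$n_repetitions,
                         seed = config$seed), list(f))
  })

  run_stage("mi", function() {
    if (is.null(state$mhc_mat)) stop("mi stage requires mhc_fasta")
    mi <- mutual_information(state$tcr_mat, state$mhc_mat,
                             pairing = "random",
                             n_repetitions = config$n_repetitions,
                             seed = config$seed)
    long <- data.frame(
      tcr_column = rep(seq_len(nrow(mi$mean)), ncol(mi$mean)),
      mhc_column = rep(seq_len(ncol(mi$mean)), each = nrow(mi$mean)),
      mean_bits = as.vector(mi$mean), std_bits = as.vector(mi$std))
    f <- out_path("mutual_information.csv")
    utils::write.csv(long, f, row.names = FALSE)
    note("mi", list(pairing = "random",
                    n_repetitions = config$n_repetitions,
                    seed = config$seed), list(f))
  })

  run_stage("biophys", function() {
    tab <- normalize_table(switch(config$property,
                                  charge = charge_table(),
                                  hydropathy = hydropathy_table(),
                                  read_property_table(config$property)))
    prof <- position_property_profile(state$tcr_mat, tab)
    f <- out_path("property_profile.csv")
    utils::write.csv(prof, f, row.names = FALSE)
    note("biophys", list(property = config$property), list(f))
  })

  run_stage("potential", function() {
    if (is.null(state$mhc)) stop("potential stage requires mhc_fasta")
    tab <- gene_allele_scores(state$tcr, state$mhc,
                              loops = intersect(c("CDR1", "CDR2"),
                                                names(state$tcr)),
                              helices = intersect(c("helix1", "helix2"),
                                                  names(state$mhc)))
    f <- out_path("interaction_scores.csv")
    utils::write.csv(tab, f, row.names = FALSE)
    state$scores <- tab
    note("potential", list(n_tcr = nrow(state$tcr),
                           n_mhc = nrow(state$mhc)), list(f))
  })

  run_stage("breakdown", function() {
    if (is.null(state$mhc)) stop("breakdown stage requires mhc_fasta")
    bd <- per_residue_breakdown(state$tcr, state$mhc,
                                loops = intersect(c("CDR1", "CDR2"),
                                                  names(state$tcr)),
                                helices = intersect(c("helix1", "helix2"),
                                                    names(state$mhc)))
    f <- out_path("per_residue_breakdown.csv")
    utils::write.csv(bd, f, row.names = FALSE)
    note("breakdown", list(), list(f))
  })

  run_stage("contacts", function() {
    recs <- lapply(config$structures, function(s) {
      ann <- if (is.character(s$annotation)) {
        read_complex_annotation(s$annotation)
      } else s$annotation
      r <- find_contacts(s$pdb, ann)
      r$structure <- s$pdb
      r
    })
    all_rec <- do.call(rbind, recs)
    f1 <- out_path("contacts.csv")
    utils::write.csv(all_rec, f1, row.names = FALSE)
    cm <- contact_count_matrix(all_rec)
    f2 <- out_path("contact_count_matrix.csv")
    utils::write.csv(data.frame(mhc_aa = rownames(cm$symmetrized),
                                cm$symmetrized, check.names = FALSE),
                     f2, row.names = FALSE)
    state$contacts <- all_rec
    note("contacts", list(n_structures = length(config$structures),
                          vdw_cutoff = 4.5, elec_cutoff = 6.0),
         list(f1, f2))
  })

  run_stage("compare", function() {
    if (is.null(state$contacts) || is.null(state$scores)) {
      stop("compare stage requires the contacts and potential stages")
    }
    per_struct <- as.data.frame(table(state$contacts$structure),
                                stringsAsFactors = FALSE)
    names(per_struct) <- c("structure", "contacts")
    gene_pot <- stats::aggregate(score ~ tcr_gene, data = state$scores,
                                 FUN = mean)
    genes <- vapply(config$structures, function(s)
      if (!is.null(s$gene)) s$gene else NA_character_, "")
    per_struct$gene <- genes[match(per_struct$structure,
                                   vapply(config$structures, `[[`, "",
                                          "pdb"))]
    per_struct$potential <- gene_pot$score[match(per_struct$gene,
                                                 gene_pot$tcr_gene)]
    per_struct <- per_struct[!is.na(per_struct$potential), , drop = FALSE]
    bins <- potential_bins(per_struct$potential)
    res <- group_comparison(per_struct$contacts, bins,
                            n_perm = config$n_perm, seed = config$seed)
    f <- out_path("group_comparison.csv")
    utils::write.csv(res, f, row.names = FALSE)
    note("compare", list(n_perm = config$n_perm, seed = config$seed),
         list(f))
  })

  invisible(manifest)
}
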