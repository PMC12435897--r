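#' Default pipeline configuration
#'
#' All analysis thresholds surfaced in one place, set to the study
#' defaults: 0.50 conservation filters, 0.75 subfamily-score threshold,
#' 0.5 putative-SLiM ortholog-conservation threshold, 5.0 Angstrom
#' contact cutoff, and consensus majorities derived from the column
#' counts.
#'
#' @param seed master seed for the synthetic generators and replicate
#'   partitions.
#' @param out_dir output directory for per-stage TSVs and the manifest.
#' @param stages character vector of stage names to run (any of
#'   "conservation", "subfamily", "contacts", "rmsd", "slims",
#'   "variants", "network").
#' @param ... overrides of the generator plans, passed to
#'   [generator_spec()] (\code{family}, \code{regions}, \code{complex},
#'   \code{tables}).
#' @return a named list configuration for [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("chemorun"),
                            stages = c("conservation", "subfamily",
                                       "contacts", "rmsd", "slims",
                                       "variants", "network"),
                            ...) {
  list(seed = as.integer(seed), out_dir = out_dir, stages = stages,
       thresholds = list(conservation = 0.50, subfamily = 0.75,
                         slim = 0.5, contact_cutoff = 5.0,
                         preserved_min_complexes = 2L),
       generator = generator_spec(seed = seed, ...))
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror [pipeline_config()]: \code{seed}, \code{out_dir},
#' \code{stages}, \code{thresholds} and generator plan overrides under
#' \code{family}/\code{regions}/\code{complex}/\code{tables}.
#'
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config(
    seed = if (is.null(y$seed)) 1L else as.integer(y$seed),
    out_dir = if (is.null(y$out_dir)) tempfile("chemorun") else y$out_dir,
    family = if (is.null(y$family)) list() else y$family,
    regions = if (is.null(y$regions)) list() else y$regions,
    complex = if (is.null(y$complex)) list() else y$complex,
    tables = if (is.null(y$tables)) list() else y$tables)
  if (!is.null(y$stages)) cfg$stages <- unlist(y$stages)
  if (!is.null(y$thresholds)) {
    cfg$thresholds <- utils::modifyList(cfg$thresholds, y$thresholds)
  }
  cfg
}

write_tsv <- function(df, dir, name) {
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the enabled stages in dependency order — generate, number,
#' conservation, subfamily scoring, contacts and fingerprint filters,
#' anchored RMSD, SLiM discovery, variant and mutational-scan summaries,
#' network analysis — writing one TSV per stage plus a JSON run manifest
#' (seeds, thresholds, stage status, row counts) into
#' \code{config$out_dir}. Outputs carry no timestamps, so two runs from
#' one configuration are byte-identical. A failing stage is isolated:
#' its error is recorded in the manifest and later stages that do not
#' depend on it still run.
#'
#' @param config from [pipeline_config()] or [read_pipeline_config()].
#' @return invisibly, a list of in-memory stage results plus the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  results <- list()
  status <- list()
  run_stage <- function(name, deps, fun) {
    if (!name %in% c(config$stages, "data")) {
      status[[name]] <<- "disabled"
      return(invisible(NULL))
    }
    unmet <- deps[!vapply(deps, function(d) {
      identical(status[[d]], "ok")
    }, NA)]
    if (length(unmet)) {
      status[[name]] <<- paste("skipped: dependency not met:",
                               paste(unmet, collapse = ", "))
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      status[[name]] <<- paste("failed:", conditionMessage(res))
    } else {
      results[[name]] <<- res
      status[[name]] <<- "ok"
    }
    invisible(NULL)
  }

  run_stage("data", character(0), function() {
    fam <- make_family_alignment(config$generator)
    regions <- make_motif_regions(config$generator)
    tabs <- make_tables(config$generator)
    subfams <- c(rep("CC", 3), rep("CXC", 2))
    cxs <- lapply(seq_along(subfams), function(i) {
      make_toy_complex(config$generator,
                       complex_id = paste0("cx", i),
                       subfamily = c(ligand = subfams[i],
                                     receptor = subfams[i]),
                       seed_offset = 10L + i)
    })
    names(cxs) <- paste0("cx", seq_along(cxs))
    list(family = fam, regions = regions, tables = tabs,
         complexes = cxs)
  })

  run_stage("conservation", "data", function() {
    aln <- results$data$family$aln
    prof_all <- conservation_profile(aln, set_descriptor = "all sequences")
    prof_cc <- conservation_profile(
      aln, function(r) r$subfamily == "CC", set_descriptor = "CC")
    prof_cxc <- conservation_profile(
      aln, function(r) r$subfamily == "CXC", set_descriptor = "CXC")
    write_tsv(prof_all, config$out_dir, "conservation_all.tsv")
    write_tsv(prof_cc, config$out_dir, "conservation_cc.tsv")
    write_tsv(prof_cxc, config$out_dir, "conservation_cxc.tsv")
    list(all = prof_all, cc = prof_cc, cxc = prof_cxc)
  })

  run_stage("subfamily", "data", function() {
    aln <- results$data$family$aln
    sc <- subfamily_scores(aln, threshold = th$subfamily,
                           seeds = config$seed + 0:2)
    write_tsv(sc, config$out_dir, "subfamily_scores.tsv")
    sc
  })

  run_stage("contacts", "data", function() {
    cxs <- results$data$complexes
    contacts <- lapply(cxs, function(t) {
      detect_contacts(t$cx, cutoff = th$contact_cutoff)
    })
    subfams <- vapply(cxs, function(t) t$cx$subfamily[["ligand"]], "")
    fp <- build_fingerprint(contacts, subfamilies = subfams)
    all_contacts <- do.call(rbind, contacts)
    write_tsv(all_contacts, config$out_dir, "contacts.tsv")
    fp_tab <- cbind(fp$pairs, as.data.frame(fp$presence * 1L,
                                            row.names = NULL))
    write_tsv(fp_tab, config$out_dir, "fingerprint.tsv")
    list(contacts = contacts, fingerprint = fp)
  })

  run_stage("rmsd", "contacts", function() {
    cxs <- results$data$complexes
    base <- cxs[[1]]$cx
    rows <- lapply(cxs[-1], function(t) {
      r <- anchored_rmsd(base, t$cx, anchor = "receptor")
      data.frame(complex_a = base$complex_id,
                 complex_b = t$cx$complex_id,
                 mean_deviation = r$mean_deviation,
                 anchor_rmsd = r$anchor_rmsd,
                 n_anchor = r$n_anchor, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    write_tsv(out, config$out_dir, "rmsd.tsv")
    out
  })

  run_stage("slims", "data", function() {
    reg <- results$data$regions
    cons <- fragment_conservation(reg$regions,
                                  paralog_regions = reg$reference,
                                  threshold = th$slim)
    fpf <- fragment_fingerprint(cons)
    write_tsv(cons, config$out_dir, "fragments.tsv")
    write_tsv(fpf$sharing, config$out_dir, "fragment_sharing.tsv")
    list(conservation = cons, fingerprint = fpf)
  })

  run_stage("variants", c("data", "contacts"), function() {
    vt <- results$data$tables$variants
    mapped <- map_variants(vt$data, vt$label_maps)
    vsum <- interface_variant_summary(mapped, vt$interface)
    ms <- mutscan_position_summary(results$data$tables$mutscan$data)
    cmp <- mutscan_compare(ms$substitutions$mean_enrichment,
                           ms$substitutions$label)
    write_tsv(vsum, config$out_dir, "variant_summary.tsv")
    write_tsv(ms$positions, config$out_dir, "mutscan_positions.tsv")
    list(mapped = mapped, summary = vsum, mutscan = ms,
         comparison = cmp)
  })

  run_stage("network", "data", function() {
    nw <- results$data$tables$network
    m <- filter_network(nw$data)
    coup <- subfamily_coupling_test(m, nw$subfamilies)
    write_tsv(data.frame(ligand = rownames(m)[row(m)[m]],
                         receptor = colnames(m)[col(m)[m]],
                         stringsAsFactors = FALSE),
              config$out_dir, "network_interactions.tsv")
    list(matrix = m, coupling = coup)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("chemodissect")),
    seed = config$seed, thresholds = th, stages = status,
    counts = list(
      sequences = if (!is.null(results$data)) {
        length(results$data$family$aln$seqs)
      } else {
        NA
      },
      labeled_columns = if (!is.null(results$data)) {
        sum(!is.na(results$data$family$aln$labels))
      } else {
        NA
      },
      unique_contact_pairs = if (!is.null(results$contacts)) {
        nrow(results$contacts$fingerprint$pairs)
      } else {
        NA
      },
      fragments = if (!is.null(results$slims)) {
        length(unique(results$slims$conservation$pattern))
      } else {
        NA
      }))
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
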