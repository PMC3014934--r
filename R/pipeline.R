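# End-to-end orchestration: one configuration drives simulation (or input
# loading), supermatrix construction, topology enumeration, ML + bootstrap,
# taxon-removal variants, site-rate estimation, fast-site dissection curves,
# AU/CV tests and signature scans, with a checksummed manifest of every
# artifact. All randomness flows from a single master seed; completed
# stages are skipped on re-runs when their configuration is unchanged.

#' Run the full analysis pipeline from one configuration
#'
#' @param config A named list, or the path to a YAML file holding one.
#'   Recognised blocks (all optional unless noted): `out_dir` (required),
#'   `seed` (default 1), `model` (`name`, `alpha`, `k`, `freq_mode`),
#'   `simulate` (an LBA preset: `preset = "lba-default"` plus overrides of
#'   [lba_scenario()] fields), `gene_set` (fields of [gene_set_spec()] minus
#'   tree/taxa, simulated on the LBA tree), `build_matrix` (`trim` flag),
#'   `topologies` (`mode = "enumerate"`, `rooted`), `ml` (`bootstrap_B`),
#'   `taxon_removal` (list of tip-label vectors), `rates` (flag),
#'   `dissect` (`schedule`, `B`, `min_columns`), `au` (`b_per_scale`),
#'   `cv` (`replicates`, `learn_frac`), `signatures` (`queries` named
#'   character vector, `monomer`, `anchor_reference`, `anchor`).
#' @return The run manifest (data frame: `stage`, `file`, `md5`),
#'   invisibly; also written to `manifest.tsv` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) stop("config error: out_dir is required")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  manifest <- list()
  note <- function(stage, files) {
    for (f in files) {
      manifest[[length(manifest) + 1L]] <<- data.frame(
        stage = stage, file = f,
        md5 = unname(tools::md5sum(file.path(out, f))),
        stringsAsFactors = FALSE)
    }
  }
  stage_hash <- function(stage, cfg) {
    tmp <- tempfile(); on.exit(unlink(tmp))
    yaml::write_yaml(list(stage = stage, cfg = cfg, seed = seed), tmp)
    unname(tools::md5sum(tmp))
  }
  # run `fn` unless the stage marker matches and all files exist
  with_stage <- function(stage, cfg, files, fn) {
    marker <- file.path(out, paste0(".", stage, ".done"))
    h <- stage_hash(stage, cfg)
    fresh <- file.exists(marker) && identical(readLines(marker, warn = FALSE), h) &&
      all(file.exists(file.path(out, files)))
    if (!fresh) {
      fn()
      writeLines(h, marker)
    }
    note(stage, files)
    !fresh
  }

  model_cfg <- config$model %||% list()
  model <- build_model(model_cfg$name %||% "LG",
                       freq_mode = model_cfg$freq_mode %||% "model",
                       alpha = model_cfg$alpha %||% 0.5,
                       k = model_cfg$k %||% 4L)

  state <- new.env()

  ## --- simulate -----------------------------------------------------------
  if (!is.null(config$simulate)) {
    sc_cfg <- config$simulate
    sc_args <- sc_cfg[setdiff(names(sc_cfg), "preset")]
    sc <- do.call(lba_scenario, c(sc_args, list(seed = seed)))
    files <- c("alignment.fasta", "true_tree.nwk", "truth_splits.yaml")
    with_stage("simulate", sc_cfg, files, function() {
      case <- make_lba_case(sc)
      write_alignment(case$alignment, file.path(out, "alignment.fasta"), "fasta")
      writeLines(write_newick(case$tree), file.path(out, "true_tree.nwk"))
      yaml::write_yaml(lapply(case$truth, split_key),
                       file.path(out, "truth_splits.yaml"))
    })
    state$aln <- read_alignment(file.path(out, "alignment.fasta"), "fasta")
    state$truth <- lapply(yaml::read_yaml(file.path(out, "truth_splits.yaml")),
                          parse_split)
  }

  ## --- gene set + supermatrix ---------------------------------------------
  if (!is.null(config$gene_set)) {
    gs_cfg <- config$gene_set
    if (is.null(state$aln)) stop("gene_set requires the simulate stage (shared tree)")
    tree <- parse_newick(readLines(file.path(out, "true_tree.nwk")))
    spec_args <- gs_cfg
    spec_args$taxa <- tree$tip.label
    spec_args$tree <- tree
    spec_args$seed <- derive_seed(seed, 17L)
    gspec <- do.call(gene_set_spec, spec_args)
    files <- c("supermatrix.phy", "supermatrix.partitions.tsv",
               "supermatrix.missing.tsv")
    with_stage("build_matrix", c(gs_cfg, config$build_matrix), files, function() {
      genes <- make_gene_set(gspec, model = model)
      if (isTRUE((config$build_matrix %||% list())$trim)) {
        genes <- lapply(genes, function(g) trim_blocks(g)$alignment)
      }
      sm <- concatenate(genes, tree$tip.label)
      write_supermatrix(sm, out)
    })
    state$aln <- read_alignment(file.path(out, "supermatrix.phy"),
                                "phylip-sequential")
  }

  if (is.null(state$aln)) {
    if (is.null(config$alignment)) {
      stop("config error: need simulate, gene_set or an alignment path")
    }
    state$aln <- read_alignment(config$alignment,
                                config$alignment_format %||% "fasta")
  }

  ## --- topologies ----------------------------------------------------------
  if (!is.null(config$topologies) || !is.null(config$ml) ||
      !is.null(config$dissect) || !is.null(config$rates) ||
      !is.null(config$au) || !is.null(config$cv)) {
    tp_cfg <- config$topologies %||% list()
    rooted <- isTRUE(tp_cfg$rooted)
    state$topologies <- enumerate_topologies(taxa(state$aln), rooted = rooted)
    files <- "topologies.nwk"
    with_stage("topologies", tp_cfg, files, function() {
      writeLines(vapply(state$topologies$trees, write_newick, ""),
                 file.path(out, "topologies.nwk"))
    })
  }

  ## --- ML + bootstrap ------------------------------------------------------
  if (!is.null(config$ml)) {
    ml_cfg <- if (isTRUE(config$ml)) list() else config$ml
    B <- as.integer(ml_cfg$bootstrap_B %||% 100L)
    files <- c("ml_ranking.tsv", "support_full.tsv")
    with_stage("ml", ml_cfg, files, function() {
      rank <- ml_over_topology_set(state$aln, state$topologies, model)
      utils::write.table(
        data.frame(rank = seq_along(rank$loglik), loglik = rank$loglik,
                   tree = vapply(rank$trees, write_newick, "")),
        file.path(out, "ml_ranking.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      bs <- bootstrap(state$aln, state$topologies, model, B = B,
                      seed = derive_seed(seed, 23L))
      write_support_table(bs, file.path(out, "support_full.tsv"))
    })

    for (ti in seq_along(config$taxon_removal %||% list())) {
      drop <- as.character(config$taxon_removal[[ti]])
      fn <- sprintf("support_drop_%s.tsv", paste(drop, collapse = "_"))
      with_stage(paste0("taxon_removal_", ti), drop, fn, function() {
        keep <- setdiff(taxa(state$aln), drop)
        sub <- state$aln[keep, , drop = FALSE]
        topo <- enumerate_topologies(keep, rooted = FALSE)
        bs <- bootstrap(sub, topo, model, B = B,
                        seed = derive_seed(seed, 23L + ti))
        write_support_table(bs, file.path(out, fn))
      })
    }
  }

  ## --- site rates + dissection ---------------------------------------------
  if (!is.null(config$rates) || !is.null(config$dissect)) {
    with_stage("rates", config$rates %||% TRUE, "site_rates.tsv", function() {
      r <- mean_rates_over_set(state$aln, state$topologies, model)
      utils::write.table(data.frame(site = seq_along(r), rate = as.numeric(r)),
                         file.path(out, "site_rates.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    })
    state$rates <- structure(
      utils::read.table(file.path(out, "site_rates.tsv"), header = TRUE,
                        sep = "\t")$rate, class = "site_rates")
  }

  if (!is.null(config$dissect)) {
    ds <- config$dissect
    sched <- if (is.null(ds$schedule) || identical(ds$schedule, "default")) {
      default_schedule()
    } else removal_schedule(ds$schedule)
    monitored <- if (!is.null(ds$monitor)) {
      lapply(ds$monitor, parse_split)
    } else if (!is.null(state$truth)) {
      state$truth
    } else stop("config error: dissect needs monitored splits")
    with_stage("dissect", ds, "support_curve.tsv", function() {
      sc <- support_curves(state$aln, state$rates, sched, monitored,
                           state$topologies, model,
                           B = as.integer(ds$B %||% 100L),
                           seed = derive_seed(seed, 31L),
                           min_columns = as.integer(ds$min_columns %||% 50L))
      utils::write.table(as.data.frame(sc), file.path(out, "support_curve.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  ## --- AU test --------------------------------------------------------------
  if (!is.null(config$au)) {
    au_cfg <- if (isTRUE(config$au)) list() else config$au
    with_stage("au", au_cfg, "au_test.tsv", function() {
      rank <- ml_over_topology_set(state$aln, state$topologies, model)
      n_cand <- min(as.integer(au_cfg$candidates %||% 2L), length(rank$trees))
      lnl <- do.call(rbind, lapply(seq_len(n_cand), function(i) {
        site_loglik(state$aln, rank$trees[[i]], model)$per_site
      }))
      rownames(lnl) <- paste0("rank", seq_len(n_cand))
      res <- au_test(lnl, b_per_scale = as.integer(au_cfg$b_per_scale %||% 1000L),
                     seed = derive_seed(seed, 41L))
      utils::write.table(as.data.frame(res), file.path(out, "au_test.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  ## --- cross-validation ------------------------------------------------------
  if (!is.null(config$cv)) {
    cv_cfg <- if (isTRUE(config$cv)) list() else config$cv
    with_stage("cv", cv_cfg, "cv_result.tsv", function() {
      rank <- ml_over_topology_set(state$aln, state$topologies, model)
      res <- cross_validate(state$aln,
                            list(model = model, tree = rank$trees[[1]]),
                            list(model = model, tree = rank$trees[[2]]),
                            replicates = as.integer(cv_cfg$replicates %||% 10L),
                            learn_frac = cv_cfg$learn_frac %||% 0.9,
                            seed = derive_seed(seed, 43L))
      utils::write.table(
        data.frame(replicate = seq_along(res$deltas), delta = res$deltas,
                   mean = res$mean, sd = res$sd),
        file.path(out, "cv_result.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    })
  }

  ## --- signatures ------------------------------------------------------------
  if (!is.null(config$signatures)) {
    sg <- config$signatures
    with_stage("signatures", sg, "signatures.tsv", function() {
      monomer <- sg$monomer %||% ubiquitin_monomer()
      rows <- lapply(names(sg$queries), function(nm) {
        rep_ <- scan_tandem_insertions(sg$queries[[nm]], monomer)
        data.frame(query = nm, monomers = rep_$monomer_count,
                   insertions = paste(rep_$junctions$insertion, collapse = ";"))
      })
      utils::write.table(do.call(rbind, rows), file.path(out, "signatures.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  manifest <- do.call(rbind, manifest)
  utils::write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

write_support_table <- function(bs, path) {
  utils::write.table(
    data.frame(split = names(bs$bipartition_support),
               support = unname(bs$bipartition_support)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
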