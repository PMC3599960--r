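#' Default pipeline configuration
#'
#' Returns the full configuration list with the documented defaults;
#' `run_pipeline()` merges user settings over these. Paths may be omitted
#' when matrices are passed directly.
#'
#' @return named list of settings.
#' @export
default_config <- function() {
  list(
    expression = NULL,       # path to expression TSV or a matrix
    annotation = NULL,       # path to sample->condition TSV or named vector
    present_calls = NULL,    # optional pc TSV path or matrix
    gmt = NULL,              # optional GMT path or named list of sets
    scale = "linear",        # or "log10"
    normalize = "before",    # quantile normalization placement
    grid = c(60L, 60L),
    presentations = 250000L,
    rate_max = 0.05, rate_min = 0.01,
    radius_min = 1.5,
    quantile = 0.98,
    lambda = 0.5,
    lpe_window = 200L,
    se_mode = "approx",
    n_list_min = 10L, n_set_min = 10L,
    permutations = 1000L,
    hg_tail = "greater",
    top_sets = 3L,
    samples = NULL,          # optional condition subset (zoom-in)
    seed = 42L,
    out_dir = "somportraits_report",
    write_portraits = TRUE
  )
}

read_yaml_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$grid)) cfg$grid <- as.integer(cfg$grid)
  cfg
}

#' Run the full portrait pipeline
#'
#' Orchestrates preprocessing, SOM training, portrait and summary-map
#' rendering, spot detection, differential expression scoring, ranked-list
#' comparison, gene-set enrichment and special-set selection, writing a
#' report directory of TSV tables and PNG images plus a JSON run manifest
#' with per-stage timings. Supplying `samples` reruns the identical
#' pipeline on a condition subset (zoom-in) with the same grid size.
#'
#' @param config list of settings (see [default_config()]) or a YAML path.
#' @return invisibly, a list with the main in-memory results (`prep`,
#'   `som`, `spots`, `scores`, `enrichment`, `special_sets`, `manifest`).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_yaml_config(config)
  cfg <- utils::modifyList(default_config(), config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfg_echo <- lapply(cfg, function(v) {
    if (is.null(v) || (is.atomic(v) && length(v) <= 4L)) v
    else sprintf("<%s of length %d>", class(v)[1L], length(v))
  })
  manifest <- list(config = cfg_echo, stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s (artifacts so far in %s)",
                   name, conditionMessage(e), out), call. = FALSE))
    manifest$stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  ## ---- preprocess ----
  prep <- t_stage("preprocess", {
    raw <- if (is.character(cfg$expression)) read_expression(cfg$expression)
           else as.matrix(cfg$expression)
    ann <- if (is.character(cfg$annotation) && length(cfg$annotation) == 1L &&
               is.null(names(cfg$annotation)))
      read_sample_annotation(cfg$annotation)
    else cfg$annotation
    conditions <- unname(ann[colnames(raw)])
    if (anyNA(conditions)) stop("annotation missing for some sample columns")
    if (!is.null(cfg$samples)) {  # zoom-in: keep only selected conditions
      keep <- conditions %in% cfg$samples
      raw <- raw[, keep, drop = FALSE]
      conditions <- conditions[keep]
    }
    preprocess_expression(raw, conditions, scale = cfg$scale,
                          normalize = cfg$normalize)
  })
  write_matrix_tsv(round(prep$delta, 6), file.path(out, "delta_expression.tsv"))

  ## ---- SOM ----
  som <- t_stage("som", {
    sched <- som_schedule(presentations = cfg$presentations,
                          rate_max = cfg$rate_max, rate_min = cfg$rate_min,
                          radius_min = cfg$radius_min, seed = cfg$seed)
    train_som(prep$delta, dims = cfg$grid, schedule = sched)
  })
  write_som_weights(som$grid, file.path(out, "metagene_weights.tsv"))

  ## ---- portraits ----
  t_stage("portraits", {
    mask <- som$assignment$n_k == 0L
    if (cfg$write_portraits) {
      dir.create(file.path(out, "portraits"), showWarnings = FALSE)
      for (m in som$samples) {
        mo <- render_mosaic(metagene_expression_state(som$grid, m),
                            som$dims, mask)
        write_mosaic_png(mo, file.path(out, "portraits",
                                       paste0(m, ".png")))
        write_mosaic_tsv(mo, file.path(out, "portraits",
                                       paste0(m, ".tsv")))
      }
    }
    sm <- summary_maps(som$grid)
    for (side in c("over", "under")) {
      mo <- render_mosaic(sm[[side]], som$dims, mask)
      write_mosaic_png(mo, file.path(out, paste0("summary_", side, ".png")))
      write_mosaic_tsv(mo, file.path(out, paste0("summary_", side, ".tsv")))
    }
    invisible(sm)
  }) -> summaries

  ## ---- spots ----
  spots <- t_stage("spots", {
    sspots <- summary_spots(summaries, som$dims, q = cfg$quantile)
    local <- lapply(som$samples, function(m) {
      st <- metagene_expression_state(som$grid, m)
      list(over = detect_spots(st, som$dims, "over", cfg$quantile, source = m),
           under = detect_spots(st, som$dims, "under", cfg$quantile, source = m))
    })
    names(local) <- som$samples
    all_spots <- c(sspots$over, sspots$under,
                   unlist(lapply(local, function(l) c(l$over, l$under)),
                          recursive = FALSE))
    utils::write.table(spot_report(all_spots, som$assignment, som$dims),
                       file.path(out, "spots.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    dir.create(file.path(out, "spot_gene_lists"), showWarnings = FALSE)
    for (s in c(sspots$over, sspots$under)) {
      writeLines(spot_gene_list(s, som$assignment),
                 file.path(out, "spot_gene_lists",
                           sprintf("summary_%s_%s.txt", s$polarity, s$label)))
    }
    list(summary = sspots, local = local)
  })

  ## ---- differential expression ----
  scores <- t_stage("diffexpr", {
    tab <- score_table(prep, lambda = cfg$lambda, W = cfg$lpe_window,
                       se_mode = cfg$se_mode)
    write_score_table(tab, file.path(out, "score_table.tsv"))
    eta <- data.frame(sample = names(tab$fdr_estimates),
                      eta0 = vapply(tab$fdr_estimates, `[[`, 1, "eta0"),
                      percent_de = vapply(tab$fdr_estimates, `[[`, 1,
                                          "percent_de"))
    utils::write.table(eta, file.path(out, "fdr_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    grid_p <- seq(0, 1, by = 0.01)
    curves <- do.call(rbind, lapply(names(tab$fdr_estimates), function(m) {
      est <- tab$fdr_estimates[[m]]
      data.frame(sample = m, p = grid_p, fdr = fdr_local(est, grid_p),
                 Fdr = fdr_tail(est, grid_p))
    }))
    utils::write.table(curves, file.path(out, "fdr_curves.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tab
  })

  ## ---- ranked-list comparison (per sample, FC vs WAD vs t) ----
  t_stage("listcomp", {
    m1 <- som$samples[1L]
    lists <- list(logFC = rank_genes(scores$logFC[, m1])$gene,
                  WAD = rank_genes(scores$WAD[, m1])$gene,
                  t = rank_genes(scores$t[, m1])$gene)
    pv <- stats::setNames(scores$p[, m1], rownames(scores$p))
    pairs <- utils::combn(names(lists), 2L)
    r_max <- min(100L, nrow(prep$delta))
    cc <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1L, i]; b <- pairs[2L, i]
      cv <- cat_curve(lists[[a]], lists[[b]], r_max)
      data.frame(pair = paste(a, b, sep = "_vs_"), cv)
    }))
    utils::write.table(cc, file.path(out, "cat_curves.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    dp <- do.call(rbind, lapply(c("logFC", "WAD"), function(a) {
      d <- delta_p_cat(lists[[a]], lists$t, pv, r_max)
      data.frame(score = a, d)
    }))
    utils::write.table(dp, file.path(out, "delta_p_cat.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(NULL)
  })

  ## ---- gene set enrichment ----
  enrichment <- if (is.null(cfg$gmt)) NULL else t_stage("genesets", {
    universe <- rownames(prep$delta)
    collection <- if (is.character(cfg$gmt)) read_gmt(cfg$gmt, universe)
                  else lapply(cfg$gmt, intersect, y = universe)
    params <- gsz_params(cfg$n_list_min, cfg$n_set_min, cfg$permutations,
                         seed = cfg$seed)
    res <- list()
    for (m in som$samples) {
      sc <- stats::setNames(prep$delta[, m], universe)
      for (s in spots$summary$over) {
        genes <- spot_gene_list(s, som$assignment)
        if (length(genes) == 0L) next
        er <- spot_enrichment(genes, collection, sc, universe, params,
                              tail = cfg$hg_tail)
        er$sample <- m; er$spot <- s$label
        res[[length(res) + 1L]] <- er
      }
    }
    res <- if (length(res)) do.call(rbind, res) else
      data.frame(set = character(), sample = character(),
                 spot = character(), gsz_p = numeric(), hg_p = numeric())
    utils::write.table(res, file.path(out, "spot_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(res) > 0L) {
      hm_in <- data.frame(sample = res$sample, spot = res$spot,
                          set = res$set, p = res$gsz_p)
      hm <- top_three_heatmap(hm_in, top = cfg$top_sets,
                              path = file.path(out, "enrichment_heatmap.png"))
      if (!is.null(hm$matrix))
        write_matrix_tsv(hm$matrix, file.path(out, "enrichment_heatmap.tsv"),
                         id_name = "set")
    }
    res
  })

  ## ---- special gene sets ----
  specials <- t_stage("special_sets", {
    pc <- if (is.character(cfg$present_calls)) {
      m <- read_expression(cfg$present_calls); storage.mode(m) <- "integer"; m
    } else cfg$present_calls
    sets <- c(select_special_set("high_expression", delta = prep$delta),
              select_special_set("top_rank_product", e = prep$e),
              select_special_set("housekeeper_mean", e = prep$e))
    if (!is.null(pc)) {
      pc <- pc[rownames(prep$delta), colnames(prep$e), drop = FALSE]
      sets <- c(sets,
                select_special_set("absent", pc = pc),
                select_special_set("housekeeper_present", pc = pc))
    }
    write_gmt(sets, file.path(out, "special_sets.gmt"))
    sets
  })

  manifest$samples <- som$samples
  manifest$n_genes <- nrow(prep$delta)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(prep = prep, som = som, summaries = summaries,
                 spots = spots, scores = scores, enrichment = enrichment,
                 special_sets = specials, manifest = manifest,
                 out_dir = out))
}
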