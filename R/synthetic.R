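#' Planted-module truth for synthetic expression data
#'
#' Describes the generative model of the synthetic fixture: disjoint
#' modules of co-expressed genes, each upregulated (by `effect` log10
#' units) in one group of samples; a log10 baseline per gene; replicate
#' noise whose SD inflates at low expression,
#' `sd(e) = sigma0 + slope * max(0, e_knee - e)`; and a detection floor
#' for the present call. Defaults give microarray-like data: baseline
#' spanning about three decades, three 100-gene modules, four sample
#' groups, three replicates.
#'
#' @param n_modules number of planted modules.
#' @param module_size genes per module.
#' @param n_groups number of sample groups (modules are active in groups
#'   1..n_modules, cycled).
#' @param effect log10 effect size of an active module.
#' @param baseline_mean,baseline_sd log10 baseline distribution.
#' @param sigma0 baseline replicate SD (log10 units).
#' @param slope SD inflation per log10 unit below `e_knee`.
#' @param e_knee expression level below which noise inflates.
#' @param replicates replicates per condition.
#' @param detection_floor log10 level for present call = 1.
#' @param seed RNG seed; the whole fixture is a pure function of it.
#' @return list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(n_modules = 3L, module_size = 100L,
                            n_groups = 4L, effect = 1.0,
                            baseline_mean = 2.5, baseline_sd = 0.7,
                            sigma0 = 0.05, slope = 0.15, e_knee = 2.0,
                            replicates = 3L, detection_floor = 1.5,
                            seed = 1L) {
  stopifnot(effect >= 0, n_modules >= 0L, replicates >= 1L,
            n_groups >= max(1L, n_modules))
  structure(list(n_modules = n_modules, module_size = module_size,
                 n_groups = n_groups, effect = effect,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 sigma0 = sigma0, slope = slope, e_knee = e_knee,
                 replicates = replicates, detection_floor = detection_floor,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Generate a replicated synthetic expression dataset
#'
#' Draws gene baselines, plants module effects in the active sample
#' groups, adds expression-dependent replicate noise and exponentiates to
#' the linear scale. Deterministic for a fixed truth (same seed gives
#' byte-identical matrices).
#'
#' @param truth a [synthetic_truth()].
#' @param n_genes total genes (>= total module genes).
#' @param n_samples number of conditions; assigned to groups round-robin.
#' @return list: `expr` (genes x (samples * replicates) linear-scale
#'   matrix), `conditions` (condition id per column), `annotation`
#'   (data.frame sample, condition), `pc` (genes x conditions present
#'   calls), `groups` (group per condition), `modules` (gene ids per
#'   module), `module_group` (active group per module), `truth`.
#' @export
generate_expression <- function(truth, n_genes = 5000L, n_samples = 12L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  total_mod <- truth$n_modules * truth$module_size
  if (n_genes < total_mod) stop("n_genes smaller than total module genes")
  if (n_samples < truth$n_groups) stop("need at least one sample per group")
  genes <- sprintf("g%05d", seq_len(n_genes))
  groups <- ((seq_len(n_samples) - 1L) %% truth$n_groups) + 1L
  conds <- sprintf("m%02d", seq_len(n_samples))
  modules <- if (truth$n_modules > 0L)
    split(genes[seq_len(total_mod)],
          rep(seq_len(truth$n_modules), each = truth$module_size))
  else list()
  names(modules) <- if (length(modules)) paste0("module", seq_along(modules))
  module_group <- if (truth$n_modules > 0L)
    ((seq_len(truth$n_modules) - 1L) %% truth$n_groups) + 1L
  else integer(0)

  with_seed(truth$seed, {
    e0 <- stats::rnorm(n_genes, truth$baseline_mean, truth$baseline_sd)
    mu <- matrix(e0, n_genes, n_samples)  # true mean log10 expression
    for (i in seq_along(modules)) {
      rows <- match(modules[[i]], genes)
      active <- which(groups == module_group[i])
      mu[rows, active] <- mu[rows, active] + truth$effect
    }
    sd_rep <- truth$sigma0 + truth$slope * pmax(truth$e_knee - mu, 0)
    R <- truth$replicates
    expr <- matrix(NA_real_, n_genes, n_samples * R)
    cond_of_col <- rep(conds, each = R)
    for (m in seq_len(n_samples)) {
      for (r in seq_len(R)) {
        col <- (m - 1L) * R + r
        expr[, col] <- 10^(mu[, m] + stats::rnorm(n_genes) * sd_rep[, m])
      }
    }
    rownames(expr) <- genes
    colnames(expr) <- paste0(cond_of_col, "_r", rep(seq_len(R), n_samples))
    pc <- (mu > truth$detection_floor) + 0L
    dimnames(pc) <- list(genes, conds)
    list(expr = expr, conditions = cond_of_col,
         annotation = data.frame(sample = colnames(expr),
                                 condition = cond_of_col,
                                 stringsAsFactors = FALSE),
         pc = pc, groups = groups, modules = modules,
         module_group = module_group, truth = truth)
  })
}

#' GMT of planted modules plus size-matched decoys
#'
#' One true set per planted module and `decoys` random same-size sets per
#' true set, drawn uniformly from the universe (decoys may overlap each
#' other and the modules; they are labeled `decoy<i>_<j>`).
#'
#' @param fixture output of [generate_expression()].
#' @param decoys decoy sets per module.
#' @param seed RNG seed for decoy draws.
#' @return named list of gene sets (`gene_set_collection`-compatible).
#' @export
matched_gmt <- function(fixture, decoys = 5L, seed = 1L) {
  universe <- rownames(fixture$expr)
  sets <- fixture$modules
  with_seed(seed, {
    for (i in seq_along(fixture$modules)) {
      for (j in seq_len(decoys)) {
        sets[[paste0("decoy", i, "_", j)]] <-
          sample(universe, length(fixture$modules[[i]]))
      }
    }
  })
  sets
}

#' Write a synthetic fixture to disk
#'
#' Emits the expression TSV, annotation TSV, present-call TSV, truth JSON
#' and the matched GMT into a directory.
#'
#' @param fixture output of [generate_expression()].
#' @param dir output directory (created if missing).
#' @param decoys decoys per module for the GMT.
#' @return the directory, invisibly.
#' @export
write_fixture <- function(fixture, dir, decoys = 5L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(fixture$expr, file.path(dir, "expression.tsv"))
  utils::write.table(fixture$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(fixture$pc, file.path(dir, "present_calls.tsv"))
  jsonlite::write_json(list(modules = fixture$modules,
                            module_group = fixture$module_group,
                            groups = fixture$groups,
                            seed = fixture$truth$seed),
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  write_gmt(matched_gmt(fixture, decoys, seed = fixture$truth$seed),
            file.path(dir, "sets.gmt"))
  invisible(dir)
}
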