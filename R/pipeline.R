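#' Run an end-to-end karyotype-evolution analysis
#'
#' Executes prepare -> fit -> asr -> branches (or a simulate /
#' stationary stage) from a single configuration, writing all outputs
#' and a manifest (package version, configuration, seeds) to an output
#' directory. The configuration is a named list, or the path to a
#' JSON/YAML file with the same fields.
#'
#' Recognised fields: `stage` (one of `"pipeline"`, `"simulate"`,
#' `"stationary"`), `tree` (Newick path), `karyotypes` (table path),
#' `model`, `y_max`, `method`, `focal` (list of `(x, y)` pairs),
#' `seed`, `n_starts`, `alpha`, `out_dir`, and for the simulate stage
#' `rates` (`k1..k5`), `root_state`, `n_tips`, `birth`, `death`; for
#' the stationary stage `K_f`, `K_i`.
#'
#' @param config Named list or path to a JSON/YAML config file.
#' @return Invisibly, a list of the produced artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stage <- config$stage %||% "pipeline"
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  y_max <- config$y_max %||% 35

  artifacts <- list()
  if (stage == "stationary") {
    sd <- stationary_karyotype(config$K_f, config$K_i, y_max)
    utils::write.table(as.data.frame(sd), file.path(out_dir, "stationary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(as.list(stationary_moments(sd)),
                         file.path(out_dir, "stationary_moments.json"),
                         auto_unbox = TRUE, digits = NA)
    artifacts$stationary <- sd
  } else if (stage == "simulate") {
    space <- karyo_states(y_max)
    r <- config$rates
    rates <- karyo_rates(r$k1, r$k2, r$k3, r$k4, k5 = r$k5 %||% 0)
    Q <- karyo_rate_matrix(space, rates)
    tree <- if (!is.null(config$tree)) read_newick(config$tree) else
      sim_bd_tree(config$n_tips, config$birth, config$death %||% 0, seed = seed)
    tips <- sim_karyotype_tips(tree, Q, unlist(config$root_state), seed = seed)
    df <- data.frame(species = names(tips), x = space$x[tips], y = space$y[tips])
    utils::write.table(df, file.path(out_dir, "tip_states.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_newick(tree, file.path(out_dir, "tree.nwk"))
    artifacts$tips <- tips; artifacts$tree <- tree
  } else {
    tree <- read_newick(config$tree)
    tab <- read_karyotype_table(config$karyotypes)
    filt <- filter_karyotypes(tab, seed = seed)
    space <- karyo_states(y_max)
    bound <- attach_tip_states(tree, filt$states, space)
    focal <- if (!is.null(config$focal))
      do.call(rbind, lapply(config$focal, unlist)) else NULL
    fit <- fit_karyotype_model(bound$tree, bound$tip_states,
                               model = config$model %||% "M0",
                               y_max = y_max,
                               method = config$method %||% "musse",
                               focal = focal, seed = seed,
                               n_starts = config$n_starts %||% 3)
    asr <- marginal_asr(fit, force = TRUE)
    br <- annotate_branches(fit, asr, alpha = config$alpha %||% 0.01)
    jsonlite::write_json(
      list(model = fit$model, loglik = fit$loglik, npar = fit$npar,
           converged = fit$converged, estimates = as.list(fit$estimates)),
      file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(asr$summary, file.path(out_dir, "asr_nodes.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(br, file.path(out_dir, "branches.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(filt$log, file.path(out_dir, "prepare_log.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    artifacts <- list(fit = fit, asr = asr, branches = br, prepare_log = filt$log)
  }
  manifest <- list(package = "karyograph",
                   version = as.character(utils::packageVersion("karyograph")),
                   stage = stage, seed = seed, config = config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(artifacts)
}

read_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr under the given seed without disturbing the caller's RNG
# stream (seed = NULL uses the current stream as-is)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
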