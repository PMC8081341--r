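#' Read and write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] that
#' validate what the downstream likelihood machinery needs: unique tip
#' labels, non-negative branch lengths, and (for time-calibrated
#' analyses) approximate ultrametricity. Branch lengths are in millions
#' of years throughout the package.
#'
#' @param path File path (or, for `read_newick`, a Newick string).
#' @param tree A `phylo` object.
#' @param warn_ultrametric Warn when the tip-depth spread exceeds
#'   `1e-6` times the tree height.
#' @return `read_newick` returns a `phylo`; `write_newick` returns
#'   `path` invisibly.
#' @export
read_newick <- function(path, warn_ultrametric = TRUE) {
  if (!file.exists(path) && !grepl("\\(", path))
    stop("tree file not found: ", path)
  tr <- if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)
  if (is.null(tr)) stop("failed to parse Newick input: ", path)
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels in tree")
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (any(tr$edge.length < 0)) stop("negative branch lengths are not allowed")
  if (warn_ultrametric) {
    d <- ape::node.depth.edgelength(tr)[seq_len(ape::Ntip(tr))]
    if (diff(range(d)) > 1e-6 * max(d))
      warning("tree is not ultrametric within tolerance (tip-depth spread ",
              format(diff(range(d))), ")")
  }
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a karyotype table
#'
#' Expects a TSV/CSV with header columns `species`, `2n` (diploid
#' chromosome count; alternatively `n` haploid) and `NF1` (fundamental
#' number = diploid arm count; alternatively `arms` haploid), plus
#' optional logical/0-1 flag columns `polyploid`, `meiosis_only` and
#' `sex_difference`, and optional `female_2n` / `female_NF1` giving the
#' female karyotype explicitly where the sexes differ. Multiple rows per
#' species encode inter-population variation and are resolved by
#' [filter_karyotypes()]. B chromosomes are assumed excluded upstream by
#' the curator.
#'
#' @param path File path; delimiter inferred from the extension
#'   (`.csv` comma, otherwise tab).
#' @return A data frame of karyotype records.
#' @export
read_karyotype_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"species" %in% names(tab)) stop("karyotype table needs a 'species' column")
  if (!any(c("2n", "n") %in% names(tab)))
    stop("karyotype table needs a '2n' or 'n' column")
  if (!any(c("NF1", "arms") %in% names(tab)))
    stop("karyotype table needs an 'NF1' or 'arms' column")
  tab
}

#' Resolve a species' karyotype from repeated records
#'
#' When several karyotypes are reported for one species, the chromosome
#' number is drawn uniformly at random from the observed values, and the
#' arm number is the median of the observed values when their count is
#' odd, or a uniform random pick of the two central values when the
#' count is even. Randomness comes from the session RNG; callers wanting
#' reproducibility seed it (as [filter_karyotypes()] does) and the
#' choice is recorded in its provenance log.
#'
#' @param chrom Observed haploid chromosome numbers (integer vector).
#' @param arms Observed haploid arm numbers (integer vector, same
#'   length).
#' @return A list with elements `x` (arm number) and `y` (chromosome
#'   number).
#' @examples
#' set.seed(1)
#' resolve_species_karyotype(c(24, 25, 24), c(24, 26, 28))
#' @export
resolve_species_karyotype <- function(chrom, arms) {
  if (length(chrom) < 1L || length(arms) < 1L)
    stop("need at least one karyotype record")
  y <- if (length(chrom) == 1L) chrom else chrom[sample.int(length(chrom), 1L)]
  sa <- sort(arms)
  m <- length(sa)
  x <- if (m %% 2L == 1L) {
    sa[(m + 1L) %/% 2L]
  } else {
    central <- sa[c(m %/% 2L, m %/% 2L + 1L)]
    central[sample.int(2L, 1L)]
  }
  list(x = as.integer(x), y = as.integer(y))
}

#' Filter and resolve karyotype records into tip states
#'
#' Applies the curation rules for karyotype compilations: species
#' flagged polyploid, having an odd diploid chromosome number, or
#' karyotyped only during meiosis are excluded; where a sex difference
#' is flagged the female karyotype (columns `female_2n`/`female_NF1`) is
#' used; diploid counts are halved; records whose arm number falls
#' outside `[y, 2y]` are dropped as invalid. Species with several
#' surviving records are resolved by [resolve_species_karyotype()].
#' Every drop and every random resolution is recorded in the provenance
#' log.
#'
#' @param tab Data frame from [read_karyotype_table()].
#' @param seed Seed for the random resolution steps.
#' @return A list with `states` (data frame `species`, `x`, `y`) and
#'   `log` (data frame `species`, `action`, `detail`).
#' @export
filter_karyotypes <- function(tab, seed = 1L) {
  getcol <- function(nm) if (nm %in% names(tab)) tab[[nm]] else NULL
  flag <- function(nm) {
    v <- getcol(nm)
    if (is.null(v)) rep(FALSE, nrow(tab)) else !is.na(v) & (v %in% c(TRUE, 1, "1", "TRUE", "yes"))
  }
  two_n <- getcol("2n")
  n_hap <- getcol("n")
  nf1 <- getcol("NF1")
  arms_hap <- getcol("arms")

  log <- data.frame(species = character(0), action = character(0),
                    detail = character(0), stringsAsFactors = FALSE)
  note <- function(sp, action, detail = "") {
    log <<- rbind(log, data.frame(species = sp, action = action,
                                  detail = detail, stringsAsFactors = FALSE))
  }

  polyploid <- flag("polyploid")
  meiosis <- flag("meiosis_only")
  sexdiff <- flag("sex_difference")

  n <- nrow(tab)
  y <- rep(NA_real_, n); x <- rep(NA_real_, n)
  drop <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    sp <- tab$species[i]
    if (polyploid[i]) { drop[i] <- "polyploid"; next }
    if (meiosis[i]) { drop[i] <- "meiosis_only"; next }
    d2n <- if (sexdiff[i] && "female_2n" %in% names(tab) &&
               !is.na(tab$female_2n[i])) tab$female_2n[i] else
             if (!is.null(two_n)) two_n[i] else NA
    dNF <- if (sexdiff[i] && "female_NF1" %in% names(tab) &&
               !is.na(tab$female_NF1[i])) tab$female_NF1[i] else
             if (!is.null(nf1)) nf1[i] else NA
    if (!is.na(d2n)) {
      if (d2n %% 2 != 0) { drop[i] <- "odd_2n"; next }
      y[i] <- d2n / 2
    } else if (!is.null(n_hap)) y[i] <- n_hap[i]
    if (!is.na(dNF)) x[i] <- dNF / 2 else if (!is.null(arms_hap)) x[i] <- arms_hap[i]
    if (is.na(x[i]) || is.na(y[i]) || y[i] < 1 ||
        x[i] < y[i] || x[i] > 2 * y[i] ||
        x[i] != floor(x[i]) || y[i] != floor(y[i]))
      drop[i] <- "invalid karyotype"
  }
  for (i in which(!is.na(drop))) note(tab$species[i], "dropped", drop[i])

  keep <- is.na(drop)
  states <- data.frame(species = character(0), x = integer(0), y = integer(0),
                       stringsAsFactors = FALSE)
  if (any(keep)) {
    note("", "seed", as.character(seed))
    with_seed(seed, for (sp in unique(tab$species[keep])) {
      rows <- which(keep & tab$species == sp)
      res <- resolve_species_karyotype(y[rows], x[rows])
      if (length(rows) > 1L)
        note(sp, "resolved",
             sprintf("%d records -> (%d, %d)", length(rows), res$x, res$y))
      states <- rbind(states, data.frame(species = sp, x = res$x, y = res$y,
                                         stringsAsFactors = FALSE))
    })
  }
  list(states = states, log = log)
}

#' Bind tip karyotypes to a phylogeny
#'
#' Intersects tree tip labels with the species column of a resolved
#' karyotype table (exact, case-sensitive matching), drops species whose
#' chromosome number exceeds the state space's `y_max`, and prunes the
#' tree to the remaining species.
#'
#' @param tree A `phylo`.
#' @param states Data frame with columns `species`, `x`, `y` (e.g. from
#'   [filter_karyotypes()]).
#' @param space A `karyo_space`.
#' @return A list with `tree` (pruned), `tip_states` (named integer
#'   vector of state indices, in tip order), and `log` (exclusions).
#' @export
attach_tip_states <- function(tree, states, space) {
  stopifnot(inherits(tree, "phylo"), inherits(space, "karyo_space"))
  log <- data.frame(species = character(0), reason = character(0),
                    stringsAsFactors = FALSE)
  matched <- intersect(tree$tip.label, states$species)
  for (sp in setdiff(tree$tip.label, states$species))
    log <- rbind(log, data.frame(species = sp, reason = "no karyotype",
                                 stringsAsFactors = FALSE))
  st <- states[match(matched, states$species), , drop = FALSE]
  idx <- state_index(space, st$x, st$y)
  outside <- is.na(idx)
  for (sp in st$species[outside])
    log <- rbind(log, data.frame(species = sp, reason = "outside state space",
                                 stringsAsFactors = FALSE))
  keep <- st$species[!outside]
  if (length(keep) < 3L)
    stop("fewer than 3 species match between tree and karyotype data")
  tree2 <- ape::keep.tip(tree, keep)
  tips <- idx[!outside][match(tree2$tip.label, keep)]
  names(tips) <- tree2$tip.label
  list(tree = tree2, tip_states = tips, log = log)
}
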