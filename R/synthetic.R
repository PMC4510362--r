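# Seeded synthetic data: random module catalogs whose definitions exercise
# the full grammar, and phenotype-structured genome cohorts in which groups
# of genomes complete different module sets with stated probabilities.
# These emulate the study design the classification stage expects -- e.g.
# taxon-like groups and an oxygen-requirement-like axis -- without any
# database download.

new_ko_pool <- function() {
  env <- new.env(parent = emptyenv())
  env$counter <- 0L
  env$used <- character(0)
  env
}

draw_ko <- function(pool, overlap_prob = 0) {
  if (length(pool$used) && stats::runif(1) < overlap_prob)
    return(sample(pool$used, 1L))
  pool$counter <- pool$counter + 1L
  if (pool$counter > 89999L) stop("KO vocabulary exhausted", call. = FALSE)
  ko <- sprintf("K%05d", 10000L + pool$counter)
  pool$used <- c(pool$used, ko)
  ko
}

random_unit <- function(pool, complex_prob, optional_prob, overlap_prob) {
  if (stats::runif(1) < complex_prob) {
    n_sub <- sample(2:4, 1L)
    kids <- lapply(seq_len(n_sub), function(i)
      defn_leaf(draw_ko(pool, overlap_prob)))
    if (stats::runif(1) < optional_prob)
      kids[[length(kids) + 1L]] <- defn_leaf(draw_ko(pool, overlap_prob),
                                             optional = TRUE)
    defn_node("COMPLEX", kids)
  } else {
    defn_leaf(draw_ko(pool, overlap_prob))
  }
}

random_step <- function(pool, alt_prob, complex_prob, optional_prob,
                        overlap_prob) {
  if (stats::runif(1) < alt_prob) {
    n_branch <- sample(2:3, 1L)
    defn_node("ALTERNATIVE", lapply(seq_len(n_branch), function(i)
      random_unit(pool, complex_prob, optional_prob, overlap_prob)))
  } else {
    random_unit(pool, alt_prob * 0 + complex_prob, optional_prob,
                overlap_prob)
  }
}

#' Generate a random module catalog
#'
#' Modules receive distinct synthetic IDs (`M9####`), random step counts and
#' random step structure: alternatives with probability `alt_prob`, complexes
#' of 2-4 subunits with probability `complex_prob`, and with probability
#' `optional_prob` an extra optional subunit on a complex.  KO vocabularies
#' are disjoint by default; `overlap_prob` makes modules reuse already-drawn
#' KOs, emulating enzymes shared among pathways.
#'
#' @param n_modules number of modules (>= 1).
#' @param steps_range length-2 integer range of steps per module.
#' @param alt_prob,complex_prob,optional_prob,overlap_prob probabilities in
#'   `[0, 1]`.
#' @param seed integer seed; generation is bit-identical given the seed.
#' @return a `module_catalog`.
#' @export
generate_catalog <- function(n_modules, steps_range = c(2L, 8L),
                             alt_prob = 0.3, complex_prob = 0.3,
                             optional_prob = 0, overlap_prob = 0,
                             seed = 1L) {
  stopifnot(n_modules >= 1, length(steps_range) == 2,
            steps_range[1] >= 1, steps_range[2] >= steps_range[1])
  for (p in c(alt_prob, complex_prob, optional_prob, overlap_prob))
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (n_modules > 9999L) stop("at most 9999 synthetic modules", call. = FALSE)
  set.seed(seed)
  pool <- new_ko_pool()
  classes <- c("pathway", "molecular_complex", "functional_set", "signature")
  recs <- lapply(seq_len(n_modules), function(i) {
    n_steps <- sample(steps_range[1]:steps_range[2], 1L)
    steps <- lapply(seq_len(n_steps), function(s)
      random_step(pool, alt_prob, complex_prob, optional_prob, overlap_prob))
    defn <- defn_node("SEQUENCE", steps)
    module_record(sprintf("M9%04d", i), defn,
                  name = sprintf("synthetic module %d", i),
                  module_class = sample(classes, 1L,
                                        prob = c(0.45, 0.35, 0.15, 0.05)))
  })
  module_catalog(recs)
}

#' Specify one synthetic genome group
#'
#' @param label group label (e.g. `"aerobe"`).
#' @param size number of genomes in the group (>= 1).
#' @param completion_probs per-module probability that a member completes
#'   the module: a scalar, or a vector named by module ID (unnamed modules
#'   fall back to `default_prob`).
#' @param partial_prob probability that a non-completed module is partially
#'   filled instead of empty.
#' @param partial_fraction_range fraction of steps satisfied when partial,
#'   drawn uniformly from this open interval.
#' @param default_prob completion probability for modules absent from a
#'   named `completion_probs` vector.
#' @return an object of class `group_spec`.
#' @export
group_spec <- function(label, size, completion_probs,
                       partial_prob = 0.3,
                       partial_fraction_range = c(0.2, 0.8),
                       default_prob = 0.1) {
  stopifnot(is.character(label), length(label) == 1L, size >= 1)
  if (any(completion_probs < 0 | completion_probs > 1) ||
      partial_prob < 0 || partial_prob > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (length(partial_fraction_range) != 2 ||
      partial_fraction_range[1] <= 0 || partial_fraction_range[2] >= 1 ||
      partial_fraction_range[1] > partial_fraction_range[2])
    stop("partial_fraction_range must lie within (0, 1)", call. = FALSE)
  structure(list(label = label, size = as.integer(size),
                 completion_probs = completion_probs,
                 partial_prob = partial_prob,
                 partial_fraction_range = partial_fraction_range,
                 default_prob = default_prob),
            class = "group_spec")
}

group_module_prob <- function(group, module_id) {
  p <- group$completion_probs
  if (is.null(names(p))) return(p[[1L]])
  if (module_id %in% names(p)) p[[module_id]] else group$default_prob
}

# add one satisfying assignment of `defn` to the KO accumulator
add_assignment <- function(acc, defn, copy_count_max) {
  for (st in module_steps(defn)) {
    sets <- minimal_sets(satisfying_sets(st))
    chosen <- sets[[sample.int(length(sets), 1L)]]
    for (ko in chosen) {
      cnt <- sample.int(copy_count_max, 1L)
      acc[[ko]] <- max(acc[[ko]] %||% 0L, cnt)
    }
  }
  acc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate phenotype-structured genome profiles
#'
#' For every genome, each module is fully completed (all KOs of one
#' satisfying assignment added) with its group's completion probability;
#' otherwise, with probability `partial_prob`, a uniform random subset of
#' its steps is satisfied.  Copy counts are drawn uniformly from
#' `1..copy_count_max`.
#'
#' @param catalog a `module_catalog` (sub-module references allowed).
#' @param groups list of `group_spec` objects (non-empty).
#' @param seed integer seed; generation is bit-identical given the seed.
#' @param copy_count_max maximum copy count per KO.
#' @return list with `profiles` (list of `genome_profile`) and `truth`
#'   (class `synthetic_truth`: named group labels per genome, the generator
#'   parameters and the seed).
#' @export
generate_profiles <- function(catalog, groups, seed = 1L,
                              copy_count_max = 3L) {
  if (!length(catalog)) stop("catalog must be non-empty", call. = FALSE)
  if (!length(groups)) stop("groups must be non-empty", call. = FALSE)
  if (inherits(groups, "group_spec")) groups <- list(groups)
  set.seed(seed)
  resolved <- lapply(catalog, function(m)
    resolve_submodules(m$definition, catalog))
  profiles <- list()
  labels <- character(0)
  for (g in groups) {
    for (i in seq_len(g$size)) {
      gid <- sprintf("%s_%02d", g$label, i)
      acc <- list()
      for (mid in names(catalog)) {
        defn <- resolved[[mid]]
        p <- group_module_prob(g, mid)
        if (stats::runif(1) < p) {
          acc <- add_assignment(acc, defn, copy_count_max)
        } else if (stats::runif(1) < g$partial_prob) {
          steps <- module_steps(defn)
          frac <- stats::runif(1, g$partial_fraction_range[1],
                               g$partial_fraction_range[2])
          n_fill <- floor(frac * length(steps))
          if (n_fill >= 1L) {
            pick <- sample.int(length(steps), n_fill)
            part <- defn_node("SEQUENCE", steps[pick])
            acc <- add_assignment(acc, part, copy_count_max)
          }
        }
      }
      counts <- unlist(acc)
      profiles[[gid]] <- genome_profile(gid,
        if (is.null(counts)) integer(0) else counts)
      labels[gid] <- g$label
    }
  }
  truth <- structure(list(labels = labels,
                          params = list(groups = groups,
                                        copy_count_max = copy_count_max),
                          seed = seed),
                     class = "synthetic_truth")
  list(profiles = unname(profiles), truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic truth> %d genomes, %d groups, seed %d\n",
              length(x$labels), length(unique(x$labels)), x$seed))
  invisible(x)
}
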