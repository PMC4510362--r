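# Module completion ratio (MCR) engine.
#
# A genome is a KO presence/copy-count profile; a module definition is a
# sequence of reaction steps.  A step is satisfied when the Boolean
# expression over KO presence evaluates true (all mandatory complex subunits
# / intra-step components present; any one alternative suffices; optional
# components never falsify).  The MCR is the percentage of countable steps
# satisfied; copy counts play no role in the MCR, only in module abundance.

#' Construct a genome KO profile
#'
#' @param genome_id short genome label (e.g. `"csu"`).
#' @param ko_counts named integer vector or list mapping KO identifiers to
#'   copy counts (all counts >= 1); a plain character vector of KO IDs is
#'   accepted as presence with count 1.  Absent KOs are absent keys, never
#'   zeros.
#' @return an object of class `genome_profile`.
#' @export
genome_profile <- function(genome_id, ko_counts = integer(0)) {
  if (!is.character(genome_id) || length(genome_id) != 1L || !nzchar(genome_id))
    stop("genome_id must be a non-empty string", call. = FALSE)
  if (is.character(ko_counts) && is.null(names(ko_counts))) {
    ko_counts <- stats::setNames(rep(1L, length(ko_counts)), ko_counts)
  }
  ko_counts <- unlist(ko_counts)
  if (length(ko_counts)) {
    kos <- names(ko_counts)
    bad <- kos[!is_ko_id(kos)]
    if (length(bad))
      stop("malformed KO identifiers in profile: ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    if (anyDuplicated(kos))
      stop("duplicate KO keys in profile", call. = FALSE)
    counts <- as.integer(ko_counts)
    if (any(is.na(counts)) || any(counts < 1L))
      stop("copy counts must be integers >= 1", call. = FALSE)
    ko_counts <- stats::setNames(counts, kos)
  } else ko_counts <- stats::setNames(integer(0), character(0))
  structure(list(genome_id = genome_id, ko_counts = ko_counts),
            class = "genome_profile")
}

#' @export
print.genome_profile <- function(x, ...) {
  cat(sprintf("<genome profile %s> %d KOs, %d gene copies\n",
              x$genome_id, length(x$ko_counts), sum(x$ko_counts)))
  invisible(x)
}

profile_kos <- function(profile) names(profile$ko_counts)

#' Evaluate one reaction step against a KO set
#'
#' Boolean evaluation of a (sub-module-free) step expression: a leaf is true
#' iff its KO is present; an `ALTERNATIVE` is true iff any child is true; a
#' `COMPLEX` or intra-step `SEQUENCE` is true iff all non-optional children
#' are true (optional children never falsify a node).
#'
#' @param step_expr a `module_defn` containing only KO leaves.
#' @param ko_set character vector of present KO identifiers.
#' @return logical scalar.
#' @export
step_satisfied <- function(step_expr, ko_set) {
  if (step_expr$kind == "LEAF") {
    if (is_module_id(step_expr$leaf))
      stop("unresolved sub-module leaf ", step_expr$leaf,
           "; call resolve_submodules() first", call. = FALSE)
    return(step_expr$leaf %in% ko_set)
  }
  if (step_expr$kind == "ALTERNATIVE")
    return(any(vapply(step_expr$children, step_satisfied, logical(1),
                      ko_set = ko_set)))
  # COMPLEX / intra-step SEQUENCE: every mandatory child
  for (k in step_expr$children)
    if (!k$optional && !step_satisfied(k, ko_set)) return(FALSE)
  TRUE
}

# Minimal KO sets whose presence satisfies `expr` (optional components
# ignored on the AND side, included on the OR side).  `limit` caps the
# combinatorial expansion; the cap is generous relative to real module sizes.
satisfying_sets <- function(expr, limit = 4096L) {
  if (expr$kind == "LEAF") return(list(expr$leaf))
  if (expr$kind == "ALTERNATIVE") {
    sets <- unlist(lapply(expr$children, satisfying_sets, limit = limit),
                   recursive = FALSE)
  } else {
    mandatory <- Filter(function(k) !k$optional, expr$children)
    if (!length(mandatory)) return(list(character(0)))
    sets <- list(character(0))
    for (k in mandatory) {
      ksets <- satisfying_sets(k, limit = limit)
      sets <- unlist(lapply(sets, function(s)
        lapply(ksets, function(t) unique(c(s, t)))), recursive = FALSE)
      if (length(sets) > limit)
        stop("definition too combinatorial to enumerate satisfying sets",
             call. = FALSE)
    }
  }
  sets <- lapply(sets, function(s) sort(unique(s)))
  unique(sets)
}

# drop sets that are supersets of another set
minimal_sets <- function(sets) {
  if (length(sets) <= 1L) return(sets)
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i != j && keep[i] && keep[j] &&
          length(sets[[j]]) <= length(sets[[i]]) &&
          all(sets[[j]] %in% sets[[i]]) &&
          !identical(sets[[j]], sets[[i]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  sets[keep]
}

# countable top-level steps of a resolved, normalized definition
module_steps <- function(defn) {
  kids <- defn$children
  kids[vapply(kids, has_required_leaf, logical(1))]
}

#' Compute the module completion ratio for one genome
#'
#' Resolves sub-module references, evaluates every countable reaction step
#' against the genome's KO presence set, and returns the completion ratio
#' `100 * satisfied_steps / total_steps` together with per-step diagnostics.
#' Copy counts are ignored: only KO presence matters for the MCR.
#'
#' @param module a `module_record`.
#' @param profile a `genome_profile`.
#' @param catalog optional `module_catalog` for resolving sub-module
#'   references.
#' @return an object of class `mcr_result` with fields `module_id`,
#'   `total_steps`, `satisfied_steps`, `mcr` (percentage, full precision),
#'   `step_status` (ordered logical) and `missing_kos` (for each unsatisfied
#'   step, the minimal KO sets that would complete it, with present KOs
#'   removed).
#' @examples
#' m <- module_record("M00099", "(K00850,K16370,K00918) K01624")
#' compute_mcr(m, genome_profile("toy", c(K01624 = 1)))
#' @export
compute_mcr <- function(module, profile, catalog = list()) {
  stopifnot(inherits(module, "module_record"),
            inherits(profile, "genome_profile"))
  defn <- resolve_submodules(module$definition, catalog)
  steps <- module_steps(defn)
  total <- length(steps)
  if (total == 0L)
    stop("module ", module$module_id, " has no countable steps",
         call. = FALSE)
  present <- profile_kos(profile)
  status <- vapply(steps, step_satisfied, logical(1), ko_set = present)
  missing <- vector("list", total)
  for (i in which(!status)) {
    cand <- minimal_sets(satisfying_sets(steps[[i]]))
    missing[[i]] <- lapply(cand, function(s) setdiff(s, present))
  }
  structure(list(module_id = module$module_id,
                 total_steps = total,
                 satisfied_steps = sum(status),
                 mcr = 100 * sum(status) / total,
                 step_status = status,
                 missing_kos = missing),
            class = "mcr_result")
}

#' @export
print.mcr_result <- function(x, ...) {
  cat(sprintf("<MCR %s> %s%% (%d/%d steps)\n", x$module_id,
              format_mcr(x$mcr), x$satisfied_steps, x$total_steps))
  invisible(x)
}

#' Round an MCR for display
#'
#' One decimal, half-up (so 85.714... prints as 85.7 and 87.45 as 87.5);
#' stored MCR values keep full precision.
#'
#' @param mcr numeric vector of percentages.
#' @param decimals decimal places to keep.
#' @return numeric vector rounded half-up.
#' @export
format_mcr <- function(mcr, decimals = 1) {
  f <- 10^decimals
  floor(mcr * f + 0.5) / f
}

#' Compute the genomes-by-modules MCR matrix
#'
#' @param catalog a `module_catalog`.
#' @param profiles list of `genome_profile` objects.
#' @return numeric matrix (rows: genomes, columns: modules) of MCR
#'   percentages at full precision, with dimnames set.
#' @export
compute_mcr_matrix <- function(catalog, profiles) {
  if (inherits(profiles, "genome_profile")) profiles <- list(profiles)
  if (!length(catalog) || !length(profiles))
    stop("need at least one module and one profile", call. = FALSE)
  gids <- vapply(profiles, function(p) p$genome_id, character(1))
  mids <- vapply(catalog, function(m) m$module_id, character(1))
  if (anyDuplicated(gids))
    stop("duplicate genome_id: ",
         paste(unique(gids[duplicated(gids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(mids))
    stop("duplicate module_id: ",
         paste(unique(mids[duplicated(mids)]), collapse = ", "),
         call. = FALSE)
  m <- matrix(NA_real_, nrow = length(profiles), ncol = length(catalog),
              dimnames = list(unname(gids), unname(mids)))
  presence <- lapply(profiles, profile_kos)
  for (j in seq_along(catalog)) {
    defn <- resolve_submodules(catalog[[j]]$definition, catalog)
    steps <- module_steps(defn)
    if (!length(steps))
      stop("module ", mids[j], " has no countable steps", call. = FALSE)
    for (i in seq_along(profiles)) {
      sat <- vapply(steps, step_satisfied, logical(1), ko_set = presence[[i]])
      m[i, j] <- 100 * sum(sat) / length(sat)
    }
  }
  m
}

## ---- module abundance -------------------------------------------------------

# All minimal complete assignments of a module: one satisfying set per
# countable step, unioned.
module_assignments <- function(defn, limit = 4096L) {
  steps <- module_steps(defn)
  sets <- list(character(0))
  for (st in steps) {
    ssets <- minimal_sets(satisfying_sets(st, limit = limit))
    sets <- unlist(lapply(sets, function(s)
      lapply(ssets, function(t) sort(unique(c(s, t))))), recursive = FALSE)
    sets <- unique(sets)
    if (length(sets) > limit)
      stop("definition too combinatorial for exact abundance", call. = FALSE)
  }
  minimal_sets(sets)
}

# exact maximum packing: choose assignments (with repetition) so that each
# KO copy is used at most once; assignments are tried in non-decreasing
# index order, which is sufficient because order does not matter
pack_assignments <- function(assigns, counts) {
  best <- function(counts, from) {
    top <- 0L
    for (j in from:length(assigns)) {
      s <- assigns[[j]]
      if (all(counts[s] >= 1L)) {
        counts[s] <- counts[s] - 1L
        cand <- 1L + best(counts, j)
        counts[s] <- counts[s] + 1L
        if (cand > top) top <- cand
      }
    }
    top
  }
  if (!length(assigns)) 0L else best(counts, 1L)
}

#' Count disjoint complete sets of a module in a genome
#'
#' The abundance of a module is the maximum number of mutually disjoint KO
#' assignments -- each satisfying every reaction step -- that the genome's
#' KO copy counts can support (e.g. the number of paralogous complete ABC
#' transporter operons).  It is 0 exactly when the module's MCR is below
#' 100 on the presence set, and at least 1 otherwise.
#'
#' For modules with at most `exact_leaf_limit` distinct KOs an exact
#' branch-and-bound packing is used; larger modules fall back to a greedy
#' bottleneck heuristic with a warning.
#'
#' @param module a `module_record`.
#' @param profile a `genome_profile` carrying copy counts.
#' @param catalog optional `module_catalog` for sub-module resolution.
#' @param exact_leaf_limit switch-over point between the exact search and
#'   the greedy heuristic.
#' @return non-negative integer.
#' @export
module_abundance <- function(module, profile, catalog = list(),
                             exact_leaf_limit = 12L) {
  stopifnot(inherits(module, "module_record"),
            inherits(profile, "genome_profile"))
  defn <- resolve_submodules(module$definition, catalog)
  if (compute_mcr(module, profile, catalog)$mcr < 100) return(0L)
  assigns <- module_assignments(defn)
  kos <- unique(unlist(assigns))
  counts <- stats::setNames(rep(0L, length(kos)), kos)
  have <- intersect(kos, profile_kos(profile))
  counts[have] <- profile$ko_counts[have]
  if (length(definition_kos(defn)) > exact_leaf_limit) {
    warning("module ", module$module_id, " exceeds the exact-search size; ",
            "using the greedy bottleneck heuristic", call. = FALSE)
    k <- 0L
    repeat {
      feas <- Filter(function(s) all(counts[s] >= 1L), assigns)
      if (!length(feas)) break
      bottleneck <- vapply(feas, function(s) min(counts[s]), numeric(1))
      s <- feas[[which.max(bottleneck)]]
      counts[s] <- counts[s] - 1L
      k <- k + 1L
    }
    return(k)
  }
  pack_assignments(assigns, counts)
}
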