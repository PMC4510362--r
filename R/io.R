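# Readers and writers.  All tabular formats are TSV, UTF-8, Unix newlines
# on write (CRLF tolerated on read); module catalogs travel in a
# KEGG-MODULE-like flat file with ENTRY/NAME/DEFINITION/CLASS records
# delimited by '///'.  Matrix files carry full double precision; rounding
# is presentation-only.

CLASS_KEYWORDS <- c(pathway = "Pathway", molecular_complex = "Complex",
                    functional_set = "FuncSet", signature = "Signature")

read_lines_any <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sub("\r$", "", readLines(path, warn = FALSE, encoding = "UTF-8"))
}

#' Read a module catalog from a flat file
#'
#' Records are delimited by `///`.  Recognized line prefixes: `ENTRY`
#' (module ID plus class keyword `Pathway`, `Complex`, `FuncSet` or
#' `Signature`), `NAME`, `DEFINITION` (continuation lines are indented and
#' joined with a single space) and `CLASS`.  Unrecognized prefixes are
#' skipped with a warning; a final record without `///` is accepted with a
#' warning.
#'
#' @param path flat-file path.
#' @return a `module_catalog`.
#' @export
read_module_flatfile <- function(path) {
  lines <- read_lines_any(path)
  recs <- list()
  cur <- list()
  key <- NULL
  terminated <- TRUE
  flush_record <- function(cur) {
    if (!length(cur)) return(NULL)
    if (is.null(cur$ENTRY))
      stop("flat-file record without ENTRY line in ", path, call. = FALSE)
    fields <- strsplit(trimws(cur$ENTRY), "[ \t]+")[[1]]
    mid <- fields[1]
    if (is.null(cur$DEFINITION))
      stop("record ", mid, " has no DEFINITION line", call. = FALSE)
    kw <- if (length(fields) >= 2) fields[2] else "Pathway"
    cls <- names(CLASS_KEYWORDS)[match(kw, CLASS_KEYWORDS)]
    if (is.na(cls)) {
      warning("record ", mid, ": unknown class keyword '", kw,
              "'; treating as pathway", call. = FALSE)
      cls <- "pathway"
    }
    module_record(mid, cur$DEFINITION, name = cur$NAME %||% "",
                  module_class = cls)
  }
  for (ln in lines) {
    if (grepl("^///", ln)) {
      rec <- flush_record(cur)
      if (!is.null(rec)) recs[[length(recs) + 1L]] <- rec
      cur <- list()
      key <- NULL
      terminated <- TRUE
      next
    }
    if (!nzchar(trimws(ln))) next
    terminated <- FALSE
    if (grepl("^[ \t]", ln)) {
      # continuation of the previous keyed line
      if (is.null(key)) {
        warning("continuation line with no preceding key ignored: ", ln,
                call. = FALSE)
        next
      }
      cur[[key]] <- paste(cur[[key]], trimws(ln))
      next
    }
    m <- regmatches(ln, regexec("^([A-Z_]+)[ \t]+(.*)$", ln))[[1]]
    if (length(m) != 3) {
      warning("unparseable flat-file line ignored: ", ln, call. = FALSE)
      next
    }
    key <- m[2]
    if (!key %in% c("ENTRY", "NAME", "DEFINITION", "CLASS")) {
      warning("unrecognized line prefix '", key, "' ignored", call. = FALSE)
      key <- NULL
      next
    }
    cur[[key]] <- trimws(m[3])
  }
  if (length(cur)) {
    if (!terminated)
      warning("final record in ", path, " lacks a '///' terminator",
              call. = FALSE)
    rec <- flush_record(cur)
    if (!is.null(rec)) recs[[length(recs) + 1L]] <- rec
  }
  if (!length(recs)) stop("no module records found in ", path, call. = FALSE)
  module_catalog(recs)
}

#' Write a module catalog to a flat file
#'
#' @param catalog a `module_catalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_module_flatfile <- function(catalog, path) {
  out <- character(0)
  for (rec in catalog) {
    out <- c(out,
             sprintf("ENTRY       %s  %s", rec$module_id,
                     CLASS_KEYWORDS[[rec$module_class]]),
             if (nzchar(rec$name)) sprintf("NAME        %s", rec$name),
             sprintf("DEFINITION  %s", rec$raw_definition),
             "///")
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Read a KO annotation table into a genome profile
#'
#' Expects two tab-separated columns, `gene_id` and `ko_id`; `#` comment
#' lines and blank lines are ignored.  Copy counts are aggregated per KO
#' (one per annotation row).  A gene listed with several KOs contributes
#' every listed KO (logged).
#'
#' @param path TSV path.
#' @param genome_id genome label; defaults to the file name without
#'   extension.
#' @return a `genome_profile`.
#' @export
read_ko_annotations <- function(path, genome_id = NULL) {
  if (is.null(genome_id))
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- read_lines_any(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (!length(rows))
    stop("no annotation rows in ", path, call. = FALSE)
  genes <- character(length(rows))
  kos <- character(length(rows))
  for (i in seq_along(rows)) {
    fields <- strsplit(lines[rows[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2)
      stop("line ", rows[i], " of ", path,
           ": expected gene_id<TAB>ko_id", call. = FALSE)
    genes[i] <- trimws(fields[1])
    kos[i] <- trimws(fields[2])
  }
  bad <- which(!is_ko_id(kos))
  if (length(bad))
    stop("malformed KO tokens in ", path, " at line",
         if (length(bad) > 1) "s", " ",
         paste(rows[utils::head(bad, 5)], collapse = ", "),
         ": ", paste(utils::head(kos[bad], 5), collapse = ", "),
         call. = FALSE)
  multi <- unique(genes[duplicated(genes)])
  if (length(multi))
    mcr_log("genes with multiple KO annotations retained: ",
            paste(utils::head(multi, 5), collapse = ", "),
            if (length(multi) > 5) ", ...")
  counts <- table(kos)
  genome_profile(genome_id,
                 stats::setNames(as.integer(counts), names(counts)))
}

## ---- matrix and table writers ----------------------------------------------

fmt_full <- function(x) sprintf("%.17g", x)

#' Write an MCR matrix as TSV
#'
#' Wide format: header `genome_id` followed by module IDs, one row per
#' genome.  Values are written at full double precision by default so the
#' file round-trips losslessly; set `decimals` for display-rounded output.
#'
#' @param matrix genomes-by-modules numeric matrix with dimnames.
#' @param path output path.
#' @param decimals `NA` (full precision) or a number of decimals.
#' @return `path`, invisibly.
#' @export
write_mcr_matrix <- function(matrix, path, decimals = NA) {
  stopifnot(is.matrix(matrix), !is.null(dimnames(matrix)))
  fmt <- if (is.na(decimals)) fmt_full
         else function(x) sprintf(paste0("%.", decimals, "f"),
                                  format_mcr(x, decimals))
  header <- paste(c("genome_id", colnames(matrix)), collapse = "\t")
  body <- vapply(seq_len(nrow(matrix)), function(i)
    paste(c(rownames(matrix)[i], fmt(matrix[i, ])), collapse = "\t"),
    character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read an MCR matrix written by [write_mcr_matrix()]
#'
#' @param path TSV path.
#' @return numeric matrix with genome/module dimnames.
#' @export
read_mcr_matrix <- function(path) {
  lines <- read_lines_any(path)
  if (length(lines) < 2) stop("MCR matrix file too short: ", path,
                              call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  mods <- header[-1]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  gids <- vapply(rows, `[`, character(1), 1L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]),
                   numeric(length(mods))))
  if (length(mods) == 1L) vals <- matrix(vals, ncol = 1L)
  dimnames(vals) <- list(gids, mods)
  vals
}

#' Long-format MCR table
#'
#' One row per genome-module pair with the satisfied/total step counts.
#'
#' @param catalog a `module_catalog`.
#' @param profiles list of `genome_profile`s.
#' @return data.frame with columns `genome_id`, `module_id`, `mcr`,
#'   `satisfied`, `total`.
#' @export
mcr_long_table <- function(catalog, profiles) {
  if (inherits(profiles, "genome_profile")) profiles <- list(profiles)
  rows <- list()
  for (p in profiles)
    for (m in catalog) {
      r <- compute_mcr(m, p, catalog)
      rows[[length(rows) + 1L]] <-
        data.frame(genome_id = p$genome_id, module_id = m$module_id,
                   mcr = r$mcr, satisfied = r$satisfied_steps,
                   total = r$total_steps, stringsAsFactors = FALSE)
    }
  do.call(rbind, rows)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write PCA scores, loadings and variance tables
#'
#' Emits `pca_scores.tsv`, `pca_loadings.tsv` and `pca_variance.tsv` in
#' `dir`; the variance table records the scaling mode used.
#'
#' @param pca an `mcr_pca` object.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_pca_tables <- function(pca, dir) {
  stopifnot(inherits(pca, "mcr_pca"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("pca_scores.tsv", "pca_loadings.tsv",
                            "pca_variance.tsv"))
  write_tsv(data.frame(genome_id = rownames(pca$scores),
                       pca$scores, check.names = FALSE), paths[1])
  write_tsv(data.frame(module_id = rownames(pca$loadings),
                       pca$loadings, check.names = FALSE), paths[2])
  write_tsv(data.frame(component = names(pca$variance_explained),
                       variance_pct = unname(pca$variance_explained),
                       scaling = pca$scaling), paths[3])
  invisible(paths)
}

#' Write a distance matrix as TSV
#'
#' @param dist symmetric distance matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dist, path) {
  write_mcr_matrix(dist, path)
}

#' Write cluster labels as a two-column TSV
#'
#' @param labels named vector (genome -> cluster).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_labels <- function(labels, path) {
  write_tsv(data.frame(genome_id = names(labels),
                       cluster = unname(labels)), path)
}

#' Write synthetic truth labels as a two-column TSV
#'
#' @param truth a `synthetic_truth` object or a named label vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_labels <- function(truth, path) {
  labels <- if (inherits(truth, "synthetic_truth")) truth$labels else truth
  write_tsv(data.frame(genome_id = names(labels),
                       group = unname(labels)), path)
}

#' Write a genome profile as a KO annotation TSV
#'
#' Synthesizes one gene row per KO copy (`<genome>_g0001` ...), the inverse
#' of [read_ko_annotations()].
#'
#' @param profile a `genome_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ko_annotations <- function(profile, path) {
  kos <- rep(names(profile$ko_counts), profile$ko_counts)
  genes <- sprintf("%s_g%04d", profile$genome_id, seq_along(kos))
  writeLines(c("# gene_id\tko_id",
               paste(genes, kos, sep = "\t")), path, useBytes = TRUE)
  invisible(path)
}

## ---- logging ----------------------------------------------------------------

mcr_log_level <- function() {
  getOption("mcrkit.log_level", "info")
}

mcr_log <- function(..., level = "info") {
  levels <- c(debug = 1, info = 2, warn = 3, quiet = 4)
  if (levels[[level]] >= levels[[mcr_log_level()]])
    message("[mcrkit] ", ...)
  invisible()
}
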