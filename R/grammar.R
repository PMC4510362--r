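# Boolean module-definition grammar (KEGG DEFINITION dialect).
#
# Dialect: space separates reaction steps (AND, lowest precedence), comma
# separates alternatives (OR), `+` joins complex subunits (AND, highest
# precedence), a leading `-` marks an optional (non-essential) component,
# parentheses group arbitrarily.  Inside a parenthesized group a space joins
# sub-components of the *same* step rather than opening a new step.

KO_PATTERN <- "^K[0-9]{5}$"
MODULE_PATTERN <- "^M[0-9]{5}$"

#' Test whether a token is a well-formed KO identifier
#'
#' KO identifiers are `K` followed by exactly five digits (e.g. `K00850`);
#' comparison throughout the package is case-sensitive exact match.
#'
#' @param x character vector of candidate tokens.
#' @return logical vector.
#' @export
is_ko_id <- function(x) grepl(KO_PATTERN, x)

#' Test whether a token is a well-formed module identifier
#'
#' Module identifiers are `M` followed by exactly five digits (e.g. `M00001`).
#'
#' @param x character vector of candidate tokens.
#' @return logical vector.
#' @export
is_module_id <- function(x) grepl(MODULE_PATTERN, x)

## ---- expression nodes -----------------------------------------------------

#' Construct a leaf node of a module definition
#'
#' @param id a KO or module identifier.
#' @param optional logical; `TRUE` marks a non-essential component.
#' @return an object of class `module_defn` with `kind = "LEAF"`.
#' @export
defn_leaf <- function(id, optional = FALSE) {
  if (!(is_ko_id(id) || is_module_id(id)))
    stop("malformed identifier for definition leaf: '", id, "'", call. = FALSE)
  structure(list(kind = "LEAF", children = list(), leaf = id,
                 optional = isTRUE(optional)),
            class = "module_defn")
}

#' Construct an internal node of a module definition
#'
#' @param kind one of `"SEQUENCE"`, `"ALTERNATIVE"`, `"COMPLEX"`.
#' @param children list of `module_defn` nodes (at least one).
#' @param optional logical; `TRUE` marks a non-essential component.
#' @return an object of class `module_defn`.
#' @export
defn_node <- function(kind, children, optional = FALSE) {
  kind <- match.arg(kind, c("SEQUENCE", "ALTERNATIVE", "COMPLEX"))
  # an empty SEQUENCE (zero steps) may be built programmatically;
  # ALTERNATIVE/COMPLEX always need children
  if (!is.list(children) ||
      (length(children) < 1 && kind != "SEQUENCE"))
    stop(kind, " node requires at least one child", call. = FALSE)
  structure(list(kind = kind, children = children, leaf = NULL,
                 optional = isTRUE(optional)),
            class = "module_defn")
}

is_defn <- function(x) inherits(x, "module_defn")

#' @export
print.module_defn <- function(x, ...) {
  cat("<module definition> ", render_definition(x), "\n", sep = "")
  invisible(x)
}

#' Structural equality of two definition trees
#'
#' Compares node kinds, child order, leaf identifiers and optional flags.
#'
#' @param a,b `module_defn` objects.
#' @return logical scalar.
#' @export
defn_equal <- function(a, b) {
  if (a$kind != b$kind || a$optional != b$optional) return(FALSE)
  if (a$kind == "LEAF") return(identical(a$leaf, b$leaf))
  if (length(a$children) != length(b$children)) return(FALSE)
  for (i in seq_along(a$children))
    if (!defn_equal(a$children[[i]], b$children[[i]])) return(FALSE)
  TRUE
}

## ---- tokenizer ------------------------------------------------------------

tokenize_definition <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == " " || ch == "\t") {
      # collapse runs of whitespace into one separator token
      j <- i
      while (j <= n && (chars[j] == " " || chars[j] == "\t")) j <- j + 1L
      toks[[length(toks) + 1L]] <- list(type = "SPACE", value = " ", pos = i)
      i <- j
    } else if (ch %in% c("(", ")", ",", "+", "-")) {
      toks[[length(toks) + 1L]] <- list(type = ch, value = ch, pos = i)
      i <- i + 1L
    } else if (ch %in% c("K", "M")) {
      frag <- paste0(chars[i:min(n, i + 5L)], collapse = "")
      if (!grepl("^[KM][0-9]{5}$", frag))
        stop("malformed token '", sub("[ ()+,\\-].*$", "", frag),
             "' at position ", i, call. = FALSE)
      # an identifier must stop after 5 digits
      if (i + 6L <= n && grepl("^[0-9A-Za-z]$", chars[i + 6L]))
        stop("malformed token starting '", frag, "' at position ", i,
             call. = FALSE)
      toks[[length(toks) + 1L]] <- list(type = "ID", value = frag, pos = i)
      i <- i + 6L
    } else {
      stop("malformed token '", ch, "' at position ", i, call. = FALSE)
    }
  }
  toks
}

## ---- recursive-descent parser ---------------------------------------------

# parser state: environment with tokens and cursor
new_parser <- function(toks) {
  env <- new.env(parent = emptyenv())
  env$toks <- toks
  env$i <- 1L
  env
}
peek_type <- function(p) if (p$i > length(p$toks)) "EOF" else p$toks[[p$i]]$type
peek_pos <- function(p) {
  if (p$i > length(p$toks)) NA_integer_ else p$toks[[p$i]]$pos
}
advance <- function(p) {
  tok <- p$toks[[p$i]]
  p$i <- p$i + 1L
  tok
}

parse_seq_node <- function(p) {
  items <- list(parse_alt_node(p))
  repeat {
    if (peek_type(p) == "SPACE") {
      advance(p)
      # lenient: trailing whitespace before ')' or end of input
      if (peek_type(p) %in% c(")", "EOF")) break
      items[[length(items) + 1L]] <- parse_alt_node(p)
    } else break
  }
  if (length(items) == 1L) items[[1L]] else defn_node("SEQUENCE", items)
}

parse_alt_node <- function(p) {
  parts <- list(parse_complex_node(p))
  while (peek_type(p) == ",") {
    advance(p)
    parts[[length(parts) + 1L]] <- parse_complex_node(p)
  }
  if (length(parts) == 1L) parts[[1L]] else defn_node("ALTERNATIVE", parts)
}

parse_complex_node <- function(p) {
  units <- list(parse_unit_node(p, optional = FALSE))
  while (peek_type(p) %in% c("+", "-")) {
    op <- advance(p)
    units[[length(units) + 1L]] <-
      parse_unit_node(p, optional = (op$type == "-"))
  }
  if (length(units) == 1L) units[[1L]] else defn_node("COMPLEX", units)
}

parse_unit_node <- function(p, optional = FALSE) {
  tt <- peek_type(p)
  if (tt == "-") {
    advance(p)
    optional <- TRUE
    tt <- peek_type(p)
  }
  if (tt == "(") {
    open <- advance(p)
    inner <- parse_seq_node(p)
    if (peek_type(p) != ")")
      stop("unbalanced parentheses: '(' at position ", open$pos,
           " is never closed", call. = FALSE)
    advance(p)
    inner$optional <- inner$optional || optional
    inner
  } else if (tt == "ID") {
    defn_leaf(advance(p)$value, optional = optional)
  } else if (tt == "EOF") {
    stop("empty step: definition ends where a component was expected",
         call. = FALSE)
  } else {
    stop("empty step: unexpected '", tt, "' at position ", peek_pos(p),
         call. = FALSE)
  }
}

#' Parse a module definition string into an expression tree
#'
#' Parses the KEGG DEFINITION dialect: space separates reaction steps,
#' comma separates alternatives, `+` joins mandatory complex subunits,
#' a leading `-` marks an optional component, and parentheses group
#' sub-expressions.  The result is normalized (see [normalize_definition()])
#' and its top level is always a `SEQUENCE` whose children are the module's
#' reaction steps.
#'
#' @param text a non-empty definition string.
#' @return a normalized `module_defn` tree with `SEQUENCE` root.
#' @examples
#' parse_definition("(K00850,K16370,K00918) K01624")
#' @export
parse_definition <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("definition must be a single character string", call. = FALSE)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty definition", call. = FALSE)
  toks <- tokenize_definition(text)
  p <- new_parser(toks)
  expr <- parse_seq_node(p)
  if (peek_type(p) != "EOF") {
    tok <- p$toks[[p$i]]
    if (tok$type == ")")
      stop("unbalanced parentheses: unmatched ')' at position ", tok$pos,
           call. = FALSE)
    stop("unexpected '", tok$value, "' at position ", tok$pos, call. = FALSE)
  }
  as_top_sequence(normalize_definition(expr))
}

as_top_sequence <- function(expr) {
  if (expr$kind == "SEQUENCE") expr else defn_node("SEQUENCE", list(expr))
}

## ---- normal form ----------------------------------------------------------

#' Normalize a definition tree
#'
#' Brings a tree to normal form: single-child internal nodes collapse to
#' their child (the optional flag is carried over), and a non-optional
#' `ALTERNATIVE` nested directly in an `ALTERNATIVE` (likewise `COMPLEX` in
#' `COMPLEX`) is flattened into its parent.  A multi-child `SEQUENCE` nested
#' inside a `SEQUENCE` is *not* flattened: it is a grouped intra-step
#' AND-component (or a substituted sub-module) and counts as a single
#' reaction step.
#'
#' @param expr a `module_defn`.
#' @return the normalized `module_defn`.
#' @export
normalize_definition <- function(expr) {
  if (expr$kind == "LEAF") return(expr)
  kids <- lapply(expr$children, normalize_definition)
  if (expr$kind %in% c("ALTERNATIVE", "COMPLEX")) {
    flat <- list()
    for (k in kids) {
      if (k$kind == expr$kind && !k$optional) flat <- c(flat, k$children)
      else flat[[length(flat) + 1L]] <- k
    }
    kids <- flat
  }
  if (length(kids) == 1L) {
    child <- kids[[1L]]
    child$optional <- child$optional || expr$optional
    return(child)
  }
  defn_node(expr$kind, kids, optional = expr$optional)
}

## ---- renderer -------------------------------------------------------------

# Render one child in the context of its parent.  Parentheses are emitted
# wherever the dialect's precedence (space < comma < plus) would otherwise
# re-associate the child, and around any optional non-leaf so the `-` prefix
# applies to the whole group.
render_child <- function(child, parent_kind) {
  txt <- render_node(child)
  wrap <- switch(parent_kind,
    SEQUENCE = child$kind %in% c("SEQUENCE", "ALTERNATIVE"),
    ALTERNATIVE = child$kind %in% c("SEQUENCE", "ALTERNATIVE"),
    COMPLEX = child$kind %in% c("SEQUENCE", "ALTERNATIVE", "COMPLEX"))
  if (wrap || (child$optional && child$kind != "LEAF"))
    txt <- paste0("(", txt, ")")
  txt
}

render_node <- function(expr) {
  if (expr$kind == "LEAF") return(expr$leaf)
  if (expr$kind == "COMPLEX") {
    first <- expr$children[[1L]]
    out <- paste0(if (first$optional) "-" else "",
                  render_child(first, "COMPLEX"))
    for (k in expr$children[-1L]) {
      sep <- if (k$optional) "-" else "+"
      out <- paste0(out, sep, render_child(k, "COMPLEX"))
    }
    return(out)
  }
  sep <- if (expr$kind == "SEQUENCE") " " else ","
  parts <- vapply(expr$children, function(k) {
    paste0(if (k$optional) "-" else "", render_child(k, expr$kind))
  }, character(1))
  paste(parts, collapse = sep)
}

#' Render a definition tree back to dialect text
#'
#' Inverse of [parse_definition()] on normalized trees:
#' `parse_definition(render_definition(e))` is structurally equal to
#' `normalize_definition(e)`.
#'
#' @param expr a `module_defn`.
#' @return a single definition string.
#' @export
render_definition <- function(expr) {
  stopifnot(is_defn(expr))
  txt <- render_node(expr)
  if (expr$optional)
    txt <- paste0("-", if (expr$kind == "LEAF") txt
                  else paste0("(", txt, ")"))
  txt
}

## ---- structural queries ---------------------------------------------------

# TRUE when a subtree contributes a required (non-optional) leaf
has_required_leaf <- function(expr) {
  if (expr$optional) return(FALSE)
  if (expr$kind == "LEAF") return(TRUE)
  any(vapply(expr$children, has_required_leaf, logical(1)))
}

#' Count the reaction steps of a module definition
#'
#' A step is a top-level child of the root `SEQUENCE` whose subtree contains
#' at least one non-optional leaf; components marked optional throughout do
#' not open a step of their own.
#'
#' @param expr a normalized `module_defn` with `SEQUENCE` root (an empty
#'   `SEQUENCE` built programmatically counts zero steps).
#' @return non-negative integer.
#' @export
count_steps <- function(expr) {
  stopifnot(is_defn(expr))
  if (expr$kind != "SEQUENCE")
    stop("count_steps expects a top-level SEQUENCE; got ", expr$kind,
         call. = FALSE)
  if (length(expr$children) == 0L) return(0L)
  sum(vapply(expr$children, has_required_leaf, logical(1)))
}

#' List the KO identifiers appearing in a definition
#'
#' @param expr a `module_defn`.
#' @param include_optional logical; drop leaves marked optional when `FALSE`.
#' @return character vector of unique KO identifiers in first-appearance
#'   order (module-identifier leaves are excluded).
#' @export
definition_kos <- function(expr, include_optional = TRUE) {
  out <- character(0)
  walk <- function(node) {
    if (!include_optional && node$optional) return(invisible())
    if (node$kind == "LEAF") {
      if (is_ko_id(node$leaf)) out[[length(out) + 1L]] <<- node$leaf
    } else lapply(node$children, walk)
    invisible()
  }
  walk(expr)
  unique(out)
}

## ---- sub-module resolution ------------------------------------------------

#' Replace module-identifier leaves by the referenced definitions
#'
#' Every leaf naming a module (an `M#####` identifier) is replaced by the
#' referenced module's full definition, wrapped as a single step component,
#' with cycle detection.  The result contains only KO leaves and is
#' normalized.
#'
#' @param expr a `module_defn`.
#' @param catalog a `module_catalog` (or named list of `module_record`s)
#'   containing every referenced module.
#' @return a `module_defn` free of module-identifier leaves.
#' @export
resolve_submodules <- function(expr, catalog = list()) {
  resolve <- function(node, active) {
    if (node$kind == "LEAF") {
      if (!is_module_id(node$leaf)) return(node)
      id <- node$leaf
      if (id %in% active)
        stop("sub-module reference cycle: ",
             paste(c(active[which(active == id):length(active)], id),
                   collapse = " -> "), call. = FALSE)
      rec <- catalog[[id]]
      if (is.null(rec))
        stop("unresolvable sub-module reference: ", id, call. = FALSE)
      sub <- resolve(rec$definition, c(active, id))
      sub$optional <- sub$optional || node$optional
      return(sub)
    }
    node$children <- lapply(node$children, resolve, active = active)
    node
  }
  as_top_sequence(normalize_definition(resolve(expr, character(0))))
}

## ---- module records and catalogs ------------------------------------------

MODULE_CLASSES <- c("pathway", "molecular_complex", "functional_set",
                    "signature")

#' Construct a module record
#'
#' Bundles a module's identity, human-readable name, class, and parsed
#' Boolean definition.
#'
#' @param module_id module identifier (`M#####`).
#' @param definition definition text in the DEFINITION dialect, or an
#'   already-parsed `module_defn`.
#' @param name free-text module name.
#' @param module_class one of `"pathway"`, `"molecular_complex"`,
#'   `"functional_set"`, `"signature"`.
#' @return an object of class `module_record`.
#' @export
module_record <- function(module_id, definition, name = "",
                          module_class = "pathway") {
  if (!is_module_id(module_id))
    stop("malformed module identifier: '", module_id, "'", call. = FALSE)
  module_class <- match.arg(module_class, MODULE_CLASSES)
  if (is.character(definition)) {
    raw <- definition
    defn <- parse_definition(definition)
  } else if (is_defn(definition)) {
    defn <- as_top_sequence(normalize_definition(definition))
    raw <- render_definition(defn)
  } else stop("definition must be text or a module_defn", call. = FALSE)
  structure(list(module_id = module_id, name = name,
                 module_class = module_class, definition = defn,
                 raw_definition = raw),
            class = "module_record")
}

#' @export
print.module_record <- function(x, ...) {
  cat(sprintf("<module %s> [%s] %s\n  DEFINITION %s\n",
              x$module_id, x$module_class, x$name, x$raw_definition))
  invisible(x)
}

#' Assemble module records into a catalog
#'
#' @param ... `module_record` objects, or a single list of them.
#' @return a named list of class `module_catalog`, keyed by module ID.
#' @export
module_catalog <- function(...) {
  recs <- list(...)
  if (length(recs) == 1L && is.list(recs[[1L]]) &&
      !inherits(recs[[1L]], "module_record"))
    recs <- recs[[1L]]
  ids <- vapply(recs, function(r) r$module_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate module_id in catalog: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(recs) <- ids
  structure(recs, class = c("module_catalog", "list"))
}

#' @export
print.module_catalog <- function(x, ...) {
  cat("<module catalog> ", length(x), " modules\n", sep = "")
  invisible(x)
}

#' @export
`[.module_catalog` <- function(x, i) {
  structure(unclass(x)[i], class = c("module_catalog", "list"))
}
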