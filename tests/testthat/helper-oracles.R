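# Independent oracles and generators used across the suite.
#
# oracle_satisfied() evaluates a definition *string* directly against a KO
# set with a tiny position-based evaluator: it never builds a tree, so it is
# an independent path against which the grammar + step evaluator are checked.

oracle_satisfied <- function(text, ko_set) {
  st <- new.env(parent = emptyenv())
  st$s <- strsplit(trimws(text), "", fixed = TRUE)[[1]]
  st$i <- 1L
  peek <- function() if (st$i > length(st$s)) "" else st$s[st$i]
  adv <- function() { ch <- st$s[st$i]; st$i <- st$i + 1L; ch }
  # returns list(v = logical, opt = logical)
  ev_unit <- function() {
    opt <- FALSE
    if (peek() == "-") { adv(); opt <- TRUE }
    if (peek() == "(") {
      adv()
      r <- ev_seq()
      stopifnot(peek() == ")")
      adv()
      list(v = r$v, opt = opt || r$opt)
    } else {
      id <- paste0(st$s[st$i:(st$i + 5L)], collapse = "")
      st$i <- st$i + 6L
      list(v = id %in% ko_set, opt = opt)
    }
  }
  ev_complex <- function() {
    parts <- list(ev_unit())
    while (peek() %in% c("+", "-")) {
      op <- adv()
      u <- ev_unit()
      if (op == "-") u$opt <- TRUE
      parts[[length(parts) + 1L]] <- u
    }
    mand <- Filter(function(p) !p$opt, parts)
    if (length(parts) == 1L) return(parts[[1L]])
    list(v = all(vapply(mand, `[[`, logical(1), "v")) || !length(mand),
         opt = FALSE)
  }
  ev_alt <- function() {
    parts <- list(ev_complex())
    while (peek() == ",") {
      adv()
      parts[[length(parts) + 1L]] <- ev_complex()
    }
    if (length(parts) == 1L) return(parts[[1L]])
    list(v = any(vapply(parts, `[[`, logical(1), "v")), opt = FALSE)
  }
  ev_seq <- function() {
    parts <- list(ev_alt())
    while (peek() == " ") {
      while (peek() == " ") adv()
      if (peek() %in% c(")", "")) break
      parts[[length(parts) + 1L]] <- ev_alt()
    }
    if (length(parts) == 1L) return(parts[[1L]])
    mand <- Filter(function(p) !p$opt, parts)
    list(v = all(vapply(mand, `[[`, logical(1), "v")) || !length(mand),
         opt = FALSE)
  }
  ev_seq()$v
}

# Random well-formed definition text, independent of the package's
# synthetic-catalog generator.  Returns the text and the leaf KOs used.
random_defn_text <- function(max_leaves = 6L, optional = FALSE) {
  new_leaf <- function() sprintf("K%05d", sample.int(99999L, 1L))
  # budget = maximum number of leaves this unit may produce
  gen_unit <- function(budget, depth) {
    if (depth > 2L || budget <= 1L || runif(1) < 0.4)
      return(new_leaf())
    n <- sample(2L:min(3L, budget), 1L)
    shares <- rep(budget %/% n, n)
    shares[1L] <- shares[1L] + budget %% n
    parts <- vapply(seq_len(n), function(i) gen_unit(shares[i], depth + 1L),
                    character(1))
    if (optional && runif(1) < 0.2)
      parts[n] <- paste0("-", parts[n])
    sep <- sample(c(",", "+", " "), 1L)
    paste0("(", paste(parts, collapse = sep), ")")
  }
  n_top <- sample.int(3L, 1L)
  budget <- max_leaves
  parts <- character(0)
  for (i in seq_len(n_top)) {
    if (budget <= 0L) break
    b <- if (i == n_top) budget else sample.int(budget, 1L)
    part <- gen_unit(b, 1L)
    parts <- c(parts, part)
    used <- length(regmatches(part, gregexpr("K[0-9]{5}", part))[[1]])
    budget <- budget - used
  }
  text <- paste(parts, collapse = " ")
  kos <- unique(regmatches(text, gregexpr("K[0-9]{5}", text))[[1]])
  list(text = text, kos = kos)
}

# Brute-force disjoint-assignment maximum for module abundance: enumerate
# every KO subset satisfying the definition text (via oracle_satisfied) and
# search the maximum packing under the copy counts.
oracle_abundance <- function(text, counts) {
  kos <- unique(regmatches(text, gregexpr("K[0-9]{5}", text))[[1]])
  subsets <- list()
  for (mask in 0:(2^length(kos) - 1L)) {
    s <- kos[bitwAnd(mask, 2^(seq_along(kos) - 1L)) > 0L]
    if (oracle_satisfied(text, s)) subsets[[length(subsets) + 1L]] <- s
  }
  if (!length(subsets)) return(0L)
  full <- stats::setNames(rep(0L, length(kos)), kos)
  have <- intersect(kos, names(counts))
  full[have] <- as.integer(counts[have])
  memo <- new.env(parent = emptyenv())
  pack <- function(cnt) {
    key <- paste(cnt, collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- 0L
    for (s in subsets) {
      if (all(cnt[s] >= 1L)) {
        cnt[s] <- cnt[s] - 1L
        cand <- 1L + pack(cnt)
        cnt[s] <- cnt[s] + 1L
        if (cand > best) best <- cand
      }
    }
    memo[[key]] <- best
    best
  }
  pack(full)
}

# Adjusted Rand index between two label vectors (independent of mclust).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_i <- sum(choose2(rowSums(tab)))
  sum_j <- sum(choose2(colSums(tab)))
  n2 <- choose2(sum(tab))
  expected <- sum_i * sum_j / n2
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}
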