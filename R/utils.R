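# Internal helpers shared across modules.

# Locale-independent (C order) sort; all user-visible orderings go through this
# so that two runs on the same input are byte-identical regardless of locale.
sortc <- function(x) sort(x, method = "radix")

EDGE_SEP <- "\t"

edge_key <- function(u, v) paste0(u, EDGE_SEP, v)

edge_unkey <- function(key) {
  parts <- strsplit(key, EDGE_SEP, fixed = TRUE)
  if (length(parts) == 1L) parts[[1L]] else parts
}

env_keys <- function(e) sortc(ls(e, all.names = TRUE, sorted = FALSE))

new_env <- function() new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x) && x >= 1

# A provenance list is a list of c(origin = <id>, start, end) triples stored as
# list(origin = chr, start = int, end = int); 0-based half-open on the ORIGINAL
# input graph's node sequences.
prov_seg <- function(origin, start, end) {
  list(origin = origin, start = as.integer(start), end = as.integer(end))
}

prov_len <- function(prov) {
  if (length(prov) == 0L) return(0L)
  sum(vapply(prov, function(s) s$end - s$start, integer(1L)))
}

# Concatenate two provenance lists, merging a contiguous junction on the same
# origin node so headers stay compact and projected paths never repeat a node.
prov_concat <- function(a, b) {
  if (length(a) == 0L) return(b)
  if (length(b) == 0L) return(a)
  la <- a[[length(a)]]
  fb <- b[[1L]]
  if (identical(la$origin, fb$origin) && la$end == fb$start) {
    a[[length(a)]] <- prov_seg(la$origin, la$start, fb$end)
    b <- b[-1L]
  }
  c(a, b)
}

# Last `len` bases of a provenance list (for prefix extension flanks).
prov_suffix <- function(prov, len) {
  need <- as.integer(len)
  out <- list()
  for (i in rev(seq_along(prov))) {
    if (need <= 0L) break
    s <- prov[[i]]
    w <- s$end - s$start
    take <- min(w, need)
    out <- c(list(prov_seg(s$origin, s$end - take, s$end)), out)
    need <- need - take
  }
  if (need > 0L) stopf("provenance shorter than requested flank (%d bases short)", need)
  out
}

# First `len` bases of a provenance list (for suffix extension flanks).
prov_prefix <- function(prov, len) {
  need <- as.integer(len)
  out <- list()
  for (s in prov) {
    if (need <= 0L) break
    w <- s$end - s$start
    take <- min(w, need)
    out <- c(out, list(prov_seg(s$origin, s$start, s$start + take)))
    need <- need - take
  }
  if (need > 0L) stopf("provenance shorter than requested flank (%d bases short)", need)
  out
}

prov_format <- function(prov) {
  paste(vapply(prov, function(s) sprintf("%s:%d-%d", s$origin, s$start, s$end),
               character(1L)), collapse = ";")
}

check_file <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  invisible(path)
}

check_dna <- function(seq, what) {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stopf("%s contains characters outside {A,C,G,T,N}: %s", what,
          paste(utils::head(which(bad)), collapse = ", "))
  }
  invisible(TRUE)
}
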