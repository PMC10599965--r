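#' Construct a gene set
#'
#' A named collection of up-genes and (optionally) down-genes. Two-part sets
#' carry both halves and are scored in opposition: the up half against the
#' expression ranking, the down half against the reversed ranking (or by
#' subtraction, method-dependent).
#'
#' @param name Set name.
#' @param up Character vector of up-gene identifiers (may be empty for
#'   down-only sets).
#' @param down Character vector of down-gene identifiers (default empty).
#' @return An object of class `gene_set` with fields `name`, `up`, `down`,
#'   and `mode` (one of `"up-only"`, `"down-only"`, `"two-part"`).
#' @export
gene_set <- function(name, up = character(), down = character()) {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  if (!length(up) && !length(down)) {
    abort(sprintf("gene set '%s' is empty", name))
  }
  both <- intersect(up, down)
  if (length(both)) {
    abort(sprintf("gene '%s' appears in both the up and down half of set '%s'",
                  both[1], name))
  }
  mode <- if (length(up) && length(down)) "two-part"
          else if (length(up)) "up-only" else "down-only"
  structure(list(name = as.character(name), up = up, down = down, mode = mode),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s (%s): %d up, %d down\n",
              x$name, x$mode, length(x$up), length(x$down)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Each line is tab-separated: name, description, then one or more genes.
#' Duplicate genes within a line are dropped; trailing whitespace and empty
#' trailing fields are ignored. All sets are read as up-only; use
#' [pair_updown_sets()] to assemble two-part signatures from `.up`/`.dn`
#' suffixed pairs.
#'
#' @param path Path to the GMT file.
#' @return A named list of [gene_set()] objects, in file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- sub("[\r[:space:]]+$", "", lines)
  keep <- nzchar(lines)
  sets <- list()
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    if (length(fields) < 3) {
      abort(sprintf("malformed GMT line %d in %s: expected >= 3 tab-separated fields, got %d",
                    i, path, length(fields)))
    }
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) {
      abort(sprintf("malformed GMT line %d in %s: gene set '%s' has no genes",
                    i, path, fields[1]))
    }
    sets[[fields[1]]] <- gene_set(fields[1], up = genes)
  }
  if (!length(sets)) abort(sprintf("no gene sets found in %s", path))
  sets
}

#' Merge suffixed up/down gene sets into two-part sets
#'
#' Sets named `"X<up_suffix>"` and `"X<down_suffix>"` are merged into a single
#' two-part [gene_set()] named `"X"`. An unpaired suffixed set becomes an
#' up-only or down-only set named `"X"`; non-suffixed sets pass through
#' unchanged.
#'
#' @param sets List of [gene_set()] objects (e.g. from [read_gmt()]).
#' @param up_suffix,down_suffix Name suffixes marking the two halves
#'   (defaults `".up"` / `".dn"`; must be non-empty and distinct).
#' @return A named list of [gene_set()] objects.
#' @export
pair_updown_sets <- function(sets, up_suffix = ".up", down_suffix = ".dn") {
  stopifnot(nzchar(up_suffix), nzchar(down_suffix))
  if (identical(up_suffix, down_suffix)) {
    abort("up_suffix and down_suffix must be distinct")
  }
  ends_with <- function(x, suf) {
    nchar(x) > nchar(suf) &&
      substring(x, nchar(x) - nchar(suf) + 1L) == suf
  }
  strip <- function(x, suf) substring(x, 1L, nchar(x) - nchar(suf))

  out <- list()
  nm <- vapply(sets, function(s) s$name, character(1))
  consumed <- logical(length(sets))
  for (i in seq_along(sets)) {
    if (consumed[i]) next
    s <- sets[[i]]
    if (ends_with(s$name, up_suffix)) {
      base <- strip(s$name, up_suffix)
      j <- which(!consumed & nm == paste0(base, down_suffix))
      if (length(j)) {
        j <- j[1]
        consumed[j] <- TRUE
        genes <- union(s$up, s$down)
        dn <- union(sets[[j]]$up, sets[[j]]$down)
        out[[base]] <- gene_set(base, up = genes, down = dn)
      } else {
        out[[base]] <- gene_set(base, up = union(s$up, s$down))
      }
    } else if (ends_with(s$name, down_suffix)) {
      base <- strip(s$name, down_suffix)
      j <- which(!consumed & nm == paste0(base, up_suffix))
      if (length(j)) {
        j <- j[1]
        consumed[j] <- TRUE
        out[[base]] <- gene_set(base, up = union(sets[[j]]$up, sets[[j]]$down),
                                down = union(s$up, s$down))
      } else {
        out[[base]] <- gene_set(base, down = union(s$up, s$down))
      }
    } else {
      out[[s$name]] <- s
    }
    consumed[i] <- TRUE
  }
  out
}

#' Restrict a gene set to the measured gene universe
#'
#' Intersects both halves with the measured genes and reports coverage, the
#' fraction of the set's genes that are measured. A coverage below 0.5 emits
#' a warning record; an empty intersection flags the set as unscorable (its
#' scores become missing values, never zeros).
#'
#' @param gs A [gene_set()].
#' @param universe Character vector of measured gene identifiers.
#' @param case_fold If `TRUE`, match identifiers case-insensitively (matching
#'   is exact and case-sensitive by default; symbol-case mismatches are a
#'   common silent failure, so the default is strict).
#' @return A list with elements `set` (the restricted [gene_set()], or `NULL`
#'   if unscorable), `coverage` (fraction measured), and `scorable` (logical).
#' @export
restrict_to_universe <- function(gs, universe, case_fold = FALSE) {
  stopifnot(inherits(gs, "gene_set"))
  if (case_fold) {
    uni_key <- toupper(universe)
    match_half <- function(h) unique(universe[match(toupper(h), uni_key, nomatch = 0L)])
  } else {
    match_half <- function(h) intersect(h, universe)
  }
  up <- match_half(gs$up)
  down <- match_half(gs$down)
  total <- length(union(gs$up, gs$down))
  coverage <- (length(up) + length(down)) / total
  if (coverage < 0.5) {
    log_record("low_coverage", set = gs$name, coverage = coverage)
    warn(sprintf("gene set '%s': only %.0f%% of its %d genes are measured",
                 gs$name, 100 * coverage, total))
  }
  if (!length(up) && !length(down)) {
    return(list(set = NULL, coverage = 0, scorable = FALSE))
  }
  list(set = gene_set(gs$name, up = up, down = down),
       coverage = coverage, scorable = TRUE)
}

#' Write gene sets to a GMT file
#'
#' Two-part sets are written as a `.up`/`.dn` suffixed pair of lines so the
#' file round-trips through [read_gmt()] + [pair_updown_sets()].
#'
#' @param sets A [gene_set()] or list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- character()
  for (s in sets) {
    if (length(s$up)) {
      nm <- if (s$mode == "two-part") paste0(s$name, ".up") else s$name
      lines <- c(lines, paste(c(nm, "na", s$up), collapse = "\t"))
    }
    if (length(s$down)) {
      nm <- paste0(s$name, ".dn")
      lines <- c(lines, paste(c(nm, "na", s$down), collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
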