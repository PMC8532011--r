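# ICD-9 / ICD-10 code-pattern engine.
#
# Clinical phenotyping rules are published as short code lists with two
# wildcard notations: a trailing "x" or "*" after a stem ("J45.x", "J44.*")
# denoting the stem itself plus any extension, and an interior "x" in
# five-character ICD-9 patterns ("250.x2") denoting exactly one arbitrary
# character at that position.  Matching is case- and dot-insensitive: both
# codes and patterns are normalized by stripping dots and uppercasing before
# comparison, because source systems disagree on dot presence.

#' Normalize an ICD code or pattern string
#'
#' Strips dots and uppercases.  All matching happens on this form.
#'
#' @param code character vector of codes
#' @return normalized character vector
#' @export
normalize_code <- function(code) {
  toupper(gsub(".", "", code, fixed = TRUE))
}

#' Compile an ICD code pattern
#'
#' @param raw pattern string as printed in a rule, e.g. `"J45.x"`,
#'   `"493.0x"`, `"250.x2"`, `"J44.*"`, `"496"`.
#' @param code_system `"icd9"` or `"icd10"`; a pattern only ever matches
#'   codes of its own system.
#' @return an object of class `code_pattern` with fields `raw`,
#'   `code_system`, `kind` (`"exact"`, `"prefix"` or `"mask"`) and the
#'   normalized matcher internals.  Compilation is idempotent: compiling the
#'   rendered `raw` again yields an identical matcher.
#' @export
#' @examples
#' p <- compile_pattern("250.x2", "icd9")
#' code_matches("250.02", "icd9", p)  # TRUE
#' code_matches("250.01", "icd9", p)  # FALSE
compile_pattern <- function(raw, code_system = c("icd9", "icd10")) {
  code_system <- match.arg(code_system)
  if (!is.character(raw) || length(raw) != 1L || !nzchar(raw)) {
    cf_stop("pattern must be a single nonempty string", "carefrag_pattern_error")
  }
  norm <- normalize_code(raw)
  chars <- strsplit(norm, "", fixed = TRUE)[[1]]
  wild <- chars %in% c("X", "*")
  kind <- "exact"
  stem <- norm
  mask_regex <- NULL
  if (any(wild)) {
    last <- length(chars)
    if (wild[1L]) {
      cf_stop(sprintf("pattern \"%s\": wildcard in leading position is not supported", raw),
              "carefrag_pattern_error")
    }
    if (wild[last]) {
      # trailing wildcard: stem plus any extension ("x" and "*" synonymous)
      if (any(wild[-last])) {
        cf_stop(sprintf("pattern \"%s\": mixed interior and trailing wildcards are not supported", raw),
                "carefrag_pattern_error")
      }
      kind <- "prefix"
      stem <- substr(norm, 1L, last - 1L)
    } else {
      # interior "x": exactly one arbitrary character per x, rest literal
      if (any(chars == "*")) {
        cf_stop(sprintf("pattern \"%s\": \"*\" is only supported in trailing position", raw),
                "carefrag_pattern_error")
      }
      kind <- "mask"
      esc <- vapply(seq_along(chars), function(i) {
        if (wild[i]) "[0-9A-Z]" else gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", chars[i])
      }, character(1))
      mask_regex <- paste0("^", paste(esc, collapse = ""), "$")
    }
  }
  structure(
    list(raw = raw, code_system = code_system, kind = kind,
         stem = stem, mask_regex = mask_regex),
    class = "code_pattern")
}

#' @export
print.code_pattern <- function(x, ...) {
  cat(sprintf("<code_pattern> %s [%s, %s]\n", x$raw, x$code_system, x$kind))
  invisible(x)
}

#' Test codes against a compiled pattern
#'
#' @param code character vector of ICD codes (dotted or dotless, any case)
#' @param code_system `"icd9"` or `"icd10"` for the codes
#' @param pattern a `code_pattern` (or a raw string, compiled on the fly
#'   with `code_system`)
#' @return logical vector: `TRUE` where the code lies in the pattern's
#'   denotation and the systems agree
#' @export
code_matches <- function(code, code_system, pattern) {
  if (is.character(pattern)) pattern <- compile_pattern(pattern, code_system)
  stopifnot(inherits(pattern, "code_pattern"))
  if (length(code) == 0L) return(logical(0))
  out <- rep(FALSE, length(code))
  sys_ok <- code_system == pattern$code_system
  if (!any(sys_ok)) return(out)
  norm <- normalize_code(code)
  hit <- switch(pattern$kind,
    exact  = norm == pattern$stem,
    prefix = startsWith(norm, pattern$stem),
    mask   = grepl(pattern$mask_regex, norm))
  out[sys_ok & hit] <- TRUE
  out
}

#' Construct a named code set
#'
#' A code set is a named bundle of patterns spanning both ICD systems, one
#' per published rule list (e.g. the COPD diagnosis list).
#'
#' @param name unique set name, e.g. `"copd_dx"`
#' @param icd9,icd10 character vectors of raw patterns per system
#' @return object of class `code_set`
#' @export
code_set <- function(name, icd9 = character(), icd10 = character()) {
  if (!nzchar(name)) cf_stop("code set name must be nonempty", "carefrag_pattern_error")
  pats <- c(lapply(icd9, compile_pattern, code_system = "icd9"),
            lapply(icd10, compile_pattern, code_system = "icd10"))
  if (length(pats) == 0L) {
    cf_stop(sprintf("code set \"%s\" has no patterns", name), "carefrag_pattern_error")
  }
  structure(list(name = name, patterns = pats), class = "code_set")
}

#' @export
print.code_set <- function(x, ...) {
  cat(sprintf("<code_set> %s: %s\n", x$name,
              paste(vapply(x$patterns, function(p)
                sprintf("%s(%s)", p$raw, p$code_system), character(1)),
                collapse = ", ")))
  invisible(x)
}

#' Shipped phenotyping vocabulary
#'
#' Reads the packaged vocabulary file (one row per pattern: set name, code
#' system, pattern) and compiles it into a named list of [code_set]s.  The
#' file is plain CSV and can be replaced without code changes.
#'
#' @param path vocabulary CSV; defaults to the packaged file
#' @return named list of `code_set` objects
#' @export
default_code_sets <- function(path = system.file("extdata", "code_sets.csv",
                                                 package = "carefrag")) {
  tab <- utils::read.csv(path, colClasses = "character")
  need <- c("code_set", "code_system", "pattern")
  if (!all(need %in% names(tab))) {
    cf_stop("vocabulary file must have columns code_set, code_system, pattern",
            "carefrag_pattern_error")
  }
  sets <- lapply(split(tab, tab$code_set), function(g) {
    code_set(g$code_set[1],
             icd9  = g$pattern[g$code_system == "icd9"],
             icd10 = g$pattern[g$code_system == "icd10"])
  })
  sets[unique(tab$code_set)]
}

#' Filter diagnosis rows by code set and row filters
#'
#' Returns the subset of `diagnosis_rows` whose code matches at least one
#' pattern of `set` under its own `code_system`, after applying optional
#' row filters.  Input row order is preserved.
#'
#' @param diagnosis_rows data.frame with at least `code`, `code_system`;
#'   optionally `rank`, `date`, `visit_id`
#' @param set a [code_set], or a set name resolved in `code_sets`
#' @param rank keep only rows with this diagnosis rank (e.g. `"principal"`)
#' @param date_range `Date` vector of length 2, inclusive window on `date`
#' @param code_sets vocabulary used to resolve a character `set`
#' @return the matching subset of `diagnosis_rows`
#' @export
any_match <- function(diagnosis_rows, set, rank = NULL, date_range = NULL,
                      code_sets = default_code_sets()) {
  if (is.character(set)) {
    if (!set %in% names(code_sets)) {
      cf_stop(sprintf("unknown code set \"%s\"", set), "carefrag_pattern_error")
    }
    set <- code_sets[[set]]
  }
  stopifnot(inherits(set, "code_set"))
  keep <- matches_set(diagnosis_rows$code, diagnosis_rows$code_system, set)
  if (!is.null(rank))  keep <- keep & diagnosis_rows$rank %in% rank
  if (!is.null(date_range)) {
    d <- diagnosis_rows$date
    keep <- keep & !is.na(d) & d >= date_range[1] & d <= date_range[2]
  }
  diagnosis_rows[keep, , drop = FALSE]
}

# Vectorized membership of codes (with per-row systems) in a code set.
# Memoizes on the unique (code, system) pairs: phenotype tables repeat codes
# heavily and this is the hot loop of label_all().
matches_set <- function(code, code_system, set) {
  if (length(code) == 0L) return(logical(0))
  key <- paste(code_system, normalize_code(code), sep = "\r")
  ukey <- unique(key)
  i <- match(ukey, key)
  ucode <- code[i]; usys <- code_system[i]
  hit <- rep(FALSE, length(ukey))
  for (p in set$patterns) {
    idx <- which(!hit & usys == p$code_system)
    if (length(idx)) hit[idx] <- code_matches(ucode[idx], usys[idx], p)
  }
  hit[match(key, ukey)]
}
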