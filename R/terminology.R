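#' Construct a code set
#'
#' A code set is a named collection of code *prefixes* in one coding
#' system (ATC for drugs, ICD-9/ICD-10 for diagnoses).  Rules and probes
#' never enumerate full codes; they match by prefix, which is how
#' hierarchical classifications such as ATC encode drug classes.
#' Published prescribing criteria are typically stated without reference
#' terminologies, so these mappings are configuration shipped alongside
#' the rule library, not logic hard-wired into the engine.
#'
#' Prefixes are matched against the literal stored code string (dots in
#' dotted ICD-9 codes are *not* removed); fixtures therefore carry dotted
#' prefixes where the stored codes are dotted.
#'
#' @param name Short identifier, e.g. `"benzodiazepines"`.
#' @param system One of `"ATC"`, `"ICD9"`, `"ICD10"`.
#' @param prefixes Character vector of non-empty code prefixes.  No prefix
#'   may be a prefix of another within the same set (that would shadow it).
#' @return An object of class `codeset`.
#' @export
codeset <- function(name, system, prefixes) {
  system <- match.arg(system, c("ATC", "ICD9", "ICD10"))
  prefixes <- toupper(trimws(as.character(prefixes)))
  if (length(prefixes) == 0L || any(!nzchar(prefixes))) {
    stop("codeset '", name, "': prefixes must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(prefixes)) {
    stop("codeset '", name, "': duplicate prefixes", call. = FALSE)
  }
  if (length(prefixes) > 1L) {
    for (i in seq_along(prefixes)) {
      shadowed <- prefixes[-i][startsWith(prefixes[-i], prefixes[i])]
      if (length(shadowed)) {
        stop("codeset '", name, "': prefix '", prefixes[i],
             "' shadows '", shadowed[1L], "'", call. = FALSE)
      }
    }
  }
  structure(list(name = name, system = system, prefixes = prefixes),
            class = "codeset")
}

#' @export
print.codeset <- function(x, ...) {
  cat(sprintf("<codeset> %s [%s]: %s\n", x$name, x$system,
              paste(x$prefixes, collapse = ", ")))
  invisible(x)
}

#' Prefix-match codes against a code set
#'
#' Case-insensitive, whitespace-stripped prefix matching.  A missing code
#' matches nothing, by contract: an uncoded (free-text) prescription is
#' invisible to every rule and probe, which is precisely the data-quality
#' failure mode the probe suite measures.
#'
#' @param codes Character vector of codes (`NA` allowed).
#' @param cs A [codeset].
#' @return Logical vector, `FALSE` wherever `codes` is `NA`.
#' @examples
#' cs <- codeset("tiotropium", "ATC", "R03BB")
#' code_matches(c("R03BB04", "R03AC02", NA), cs)  # TRUE FALSE FALSE
#' @export
code_matches <- function(codes, cs) {
  stopifnot(inherits(cs, "codeset"))
  codes <- toupper(trimws(as.character(codes)))
  out <- rep(FALSE, length(codes))
  ok <- !is.na(codes)
  if (any(ok)) {
    m <- rep(FALSE, sum(ok))
    for (p in cs$prefixes) m <- m | startsWith(codes[ok], p)
    out[ok] <- m
  }
  out
}

#' Load code sets from a YAML or JSON file
#'
#' The file maps names to `{system, prefixes}` entries.  All sets are
#' validated on load; duplicate names and shadowing prefixes are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of [codeset] objects.
#' @seealso [default_codesets()] for the bundled fixture.
#' @export
load_codesets <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (anyDuplicated(names(raw))) {
    stop("duplicate codeset names: ",
         paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(names(raw), function(nm) {
    entry <- raw[[nm]]
    if (is.null(entry$system) || is.null(entry$prefixes)) {
      stop("codeset '", nm, "': needs 'system' and 'prefixes'", call. = FALSE)
    }
    codeset(nm, entry$system, unlist(entry$prefixes))
  })
  names(out) <- names(raw)
  out
}

#' Bundled code sets
#'
#' Loads the code-set fixture shipped with the package: the drug classes
#' and diagnosis groups referenced by the default rule library and by the
#' drug-diagnosis concordance probes (tiotropium/COPD, levothyroxine/
#' hypothyroidism, anti-gout medication/gout, plus diabetes for the
#' problem-list probe).  These are conventional ATC/ICD-9 mappings;
#' clinical fidelity of any particular mapping is a terminology decision,
#' reviewable and replaceable in the YAML file.
#'
#' @return Named list of [codeset] objects.
#' @export
default_codesets <- function() {
  load_codesets(system.file("extdata", "codesets.yaml", package = "stoppcds",
                            mustWork = TRUE))
}

# Representative full code for a codeset, used by the synthetic generator
# when it must materialize a concrete record that the set will match.
# ATC prefixes are padded to the 7-character level-5 shape
# (letter, 2 digits, letter, letter, 2 digits); ICD prefixes are already
# valid stored codes under literal-prefix matching.
codeset_example_code <- function(cs) {
  p <- cs$prefixes[1L]
  if (cs$system != "ATC") return(p)
  pad <- c("A01", "01", "1", "")  # completes lengths 4..7
  n <- nchar(p)
  if (n >= 7L) return(substr(p, 1L, 7L))
  if (n == 3L) return(paste0(p, "AA01"))
  paste0(p, pad[[n - 3L]])
}
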