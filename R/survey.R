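# Phasing-method survey: free-text method normalization with seniority
# precedence, entity/date filtering, five-year double-date binning, and
# category-share reporting, plus a seeded synthetic fixture generator
# standing in for a PDB metadata extract.

#' Phasing-method categories in order of seniority
#'
#' When a method string references several methods, the most senior is
#' allocated: MIRAS > MIR > MAD > SIRAS > SIR > SAD > MR > Fourier
#' synthesis. `EXCLUDED` marks ab-initio/direct-methods entries (removed
#' from shares); `NULL` marks empty or unrecognized strings.
#'
#' @return Character vector of category names, most senior first.
#' @export
phasing_categories <- function() {
  c("MIRAS", "MIR", "MAD", "SIRAS", "SIR", "SAD", "MR", "FOURIER_SYNTHESIS",
    "EXCLUDED", "NULL")
}

.experimental_categories <- c("SAD", "MAD", "SIR", "SIRAS", "MIR", "MIRAS")

#' Default alias table mapping method-text patterns to categories
#'
#' Patterns are regular expressions matched against the canonicalized
#' string (upper case, punctuation collapsed to single spaces). The
#' dictionary ships with the alias forms a free-format method field
#' commonly contains plus obvious variants; it is extensible via
#' [read_alias_config()] and is necessarily best-effort for historical
#' free-text.
#'
#' @return Data frame with columns `pattern`, `category`.
#' @export
default_alias_table <- function() {
  data.frame(
    pattern = c(
      "\\bMIRAS\\b", "MULTIPLE ISOMORPHOUS REPLACEMENT WITH ANOMALOUS",
      "\\bMIR\\b", "MULTIPLE ISOMORPHOUS REPLACEMENT",
      "\\bMAD\\b", "MULTI ?WAVELENGTH ANOMALOUS", "MULTIPLE WAVELENGTH ANOMALOUS",
      "\\bSIRAS\\b", "SINGLE ISOMORPHOUS REPLACEMENT WITH ANOMALOUS",
      "\\bSIR\\b", "SINGLE ISOMORPHOUS REPLACEMENT",
      "\\bSAD\\b", "\\bS A D\\b", "SINGLE ?WAVELENGTH ANOMALOUS", "\\bMRSAD\\b",
      "\\bMR\\b", "MOLECULAR REPLACEMENT",
      "FOURIER SYNTHESIS", "DIFFERENCE FOURIER", "\\bFOURIER\\b",
      "\\bAB INITIO\\b", "DIRECT METHODS"
    ),
    category = c(
      "MIRAS", "MIRAS",
      "MIR", "MIR",
      "MAD", "MAD", "MAD",
      "SIRAS", "SIRAS",
      "SIR", "SIR",
      "SAD", "SAD", "SAD", "SAD",
      "MR", "MR",
      "FOURIER_SYNTHESIS", "FOURIER_SYNTHESIS", "FOURIER_SYNTHESIS",
      "EXCLUDED", "EXCLUDED"
    ),
    stringsAsFactors = FALSE
  )
}

#' Read an alias configuration file
#'
#' A CSV/TSV with columns `pattern` and `category`; rows are appended ahead
#' of the default table so user aliases take priority.
#'
#' @param path Path to the alias file.
#' @return Data frame usable as the `aliases` argument of
#'   [normalize_method()].
#' @export
read_alias_config <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("pattern", "category") %in% names(tab))) {
    stop_mrellg("alias config needs 'pattern' and 'category' columns")
  }
  bad <- setdiff(tab$category, phasing_categories())
  if (length(bad)) stop_mrellg("unknown categories in alias config: ", paste(bad, collapse = ", "))
  rbind(tab[, c("pattern", "category")], default_alias_table())
}

canonical_method <- function(text) {
  x <- toupper(text)
  x <- gsub("[^A-Z0-9]+", " ", x)
  trimws(x)
}

#' Normalize a free-text phasing-method string to a category
#'
#' Tokenizes the string, finds every category it references via the alias
#' dictionary, and returns the most senior. "SAD with molecular
#' replacement" is SAD; "SIRAS/MAD" is MAD. Ab-initio/direct-methods-only
#' strings map to `EXCLUDED`; empty, `NA`, or unrecognized strings map to
#' `NULL`. The function is total: it never errors on input text.
#'
#' @param text Character vector of method strings (may contain `NA`).
#' @param aliases Alias table (see [default_alias_table()]).
#' @return Character vector of category names.
#' @export
normalize_method <- function(text, aliases = default_alias_table()) {
  vapply(text, function(t) {
    if (is.null(t) || is.na(t)) return("NULL")
    canon <- canonical_method(t)
    if (canon == "") return("NULL")
    hits <- unique(aliases$category[vapply(aliases$pattern, grepl, logical(1), x = canon)])
    phasing <- setdiff(phasing_categories(), c("EXCLUDED", "NULL"))
    found <- phasing[phasing %in% hits]
    if (length(found)) return(found[1])       # seniority order
    if ("EXCLUDED" %in% hits) return("EXCLUDED")
    "NULL"
  }, character(1), USE.NAMES = FALSE)
}

#' Assemble survey records
#'
#' @param id,deposition_date,release_date,entity_id,method_text Aligned
#'   vectors; dates as `Date` or ISO-8601 strings.
#' @return A data frame of class `survey_records`.
#' @export
survey_records <- function(id, deposition_date, release_date, entity_id,
                           method_text) {
  out <- data.frame(id = as.character(id),
                    deposition_date = as.character(deposition_date),
                    release_date = as.character(release_date),
                    entity_id = as.character(entity_id),
                    method_text = as.character(method_text),
                    stringsAsFactors = FALSE)
  structure(out, class = c("survey_records", "data.frame"))
}

#' Read a survey metadata table
#'
#' CSV/TSV with columns `id`, `deposition_date` (ISO 8601),
#' `release_date`, `entity_id`, `method_text`.
#'
#' @param path Path to the table.
#' @return A `survey_records` data frame.
#' @export
read_survey_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("id", "deposition_date", "release_date", "entity_id", "method_text")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop_mrellg("survey table lacks column(s): ", paste(miss, collapse = ", "))
  do.call(survey_records, tab[need])
}

parse_date_safe <- function(x) {
  suppressWarnings(as.Date(x, format = "%Y-%m-%d"))
}

#' Bin survey records into double-date windows
#'
#' A record enters a window only when **both** its deposition date and its
#' release date fall inside that window (records straddling a boundary are
#' counted nowhere); only entries with entity id `"1"` are considered;
#' records dated before the start year are dropped, as are records whose
#' method normalizes to `NULL` or `EXCLUDED`. Unparseable dates trigger a
#' per-record warning and the record is dropped (the count is reported in
#' the `dropped` attribute).
#'
#' @param records A `survey_records` data frame.
#' @param start_year First year of the first window (default 2000; earlier
#'   entries are too sparse to analyse).
#' @param window_years Window width in years (default 5).
#' @param aliases Alias table for [normalize_method()].
#' @return Data frame with columns `window` (label such as "2000-2004"),
#'   `category`, `n`; attribute `dropped` summarises exclusions.
#' @export
bin_records <- function(records, start_year = 2000L, window_years = 5L,
                        aliases = default_alias_table()) {
  if (window_years < 1) stop_mrellg("window_years must be >= 1")
  dep <- parse_date_safe(records$deposition_date)
  rel <- parse_date_safe(records$release_date)
  bad_date <- is.na(dep) | is.na(rel)
  if (any(bad_date)) {
    for (i in which(bad_date)) {
      warning("record ", records$id[i], ": unparseable date(s); dropped")
    }
  }
  cat_ <- normalize_method(records$method_text, aliases)
  ydep <- as.integer(format(dep, "%Y"))
  yrel <- as.integer(format(rel, "%Y"))
  wdep <- (ydep - start_year) %/% window_years
  wrel <- (yrel - start_year) %/% window_years
  keep <- !bad_date & records$entity_id == "1" &
    ydep >= start_year & yrel >= start_year &
    wdep == wrel & !cat_ %in% c("NULL", "EXCLUDED")
  keep[is.na(keep)] <- FALSE
  dropped <- c(bad_dates = sum(bad_date, na.rm = TRUE),
               entity = sum(records$entity_id != "1", na.rm = TRUE),
               straddle_or_early = sum(!bad_date & records$entity_id == "1" &
                                         (is.na(wdep) | is.na(wrel) | wdep != wrel |
                                            ydep < start_year | yrel < start_year),
                                       na.rm = TRUE),
               null_or_excluded = sum(cat_ %in% c("NULL", "EXCLUDED")))
  w <- wdep[keep]
  if (!any(keep)) {
    tab <- data.frame(window = character(0), category = character(0), n = integer(0))
  } else {
    labels <- sprintf("%d-%d", start_year + w * window_years,
                      start_year + (w + 1L) * window_years - 1L)
    tab <- as.data.frame(table(window = labels, category = cat_[keep]),
                         stringsAsFactors = FALSE)
    names(tab)[3] <- "n"
    tab <- tab[tab$n > 0, , drop = FALSE]
  }
  structure(tab[order(tab$window, match(tab$category, phasing_categories())), ,
                drop = FALSE],
            row.names = NULL, class = "data.frame", dropped = dropped)
}

#' Per-window phasing-method shares
#'
#' With scope `"all-methods"` the shares are over three groups --
#' experimental phasing (all six experimental categories combined), MR and
#' Fourier synthesis. With scope `"experimental-only"` the shares are over
#' the six experimental categories. Shares in each non-empty window sum to
#' 100; empty windows are simply absent.
#'
#' @param binned Output of [bin_records()].
#' @param scope `"all-methods"` or `"experimental-only"`.
#' @return Data frame with columns `window`, `category`, `share` (percent).
#' @export
report_shares <- function(binned, scope = c("all-methods", "experimental-only")) {
  scope <- match.arg(scope)
  out <- list()
  for (w in unique(binned$window)) {
    sub <- binned[binned$window == w, , drop = FALSE]
    counts <- stats::setNames(sub$n, sub$category)
    if (scope == "all-methods") {
      grp <- c(EXPERIMENTAL = sum(counts[names(counts) %in% .experimental_categories]),
               MR = sum(counts[names(counts) == "MR"]),
               FOURIER_SYNTHESIS = sum(counts[names(counts) == "FOURIER_SYNTHESIS"]))
    } else {
      grp <- vapply(.experimental_categories,
                    function(cc) sum(counts[names(counts) == cc]), numeric(1))
    }
    tot <- sum(grp)
    if (tot == 0) next
    out[[w]] <- data.frame(window = w, category = names(grp),
                           share = 100 * as.numeric(grp) / tot,
                           stringsAsFactors = FALSE)
  }
  if (!length(out)) stop_mrellg("no records in any window")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.alias_pool <- list(
  MIRAS = c("MIRAS", "multiple isomorphous replacement with anomalous scattering"),
  MIR = c("MIR", "multiple isomorphous replacement"),
  MAD = c("MAD", "SIRAS/MAD", "multiwavelength anomalous dispersion"),
  SIRAS = c("SIRAS", "single isomorphous replacement with anomalous scattering"),
  SIR = c("SIR", "single isomorphous replacement"),
  SAD = c("SAD", "S.A.D.", "MRSAD", "SAD with molecular replacement",
          "single-wavelength anomalous dispersion"),
  MR = c("MR", "molecular replacement", "MOLECULAR REPLACEMENT"),
  FOURIER_SYNTHESIS = c("FOURIER SYNTHESIS", "difference Fourier")
)

#' Generate a synthetic survey fixture
#'
#' Seeded stand-in for a PDB metadata extract: records with dates inside a
#' window (or straddling into the next one, for a stated fraction), alias
#' spellings drawn from a per-category pool, and entity id "1".
#'
#' @param seed Integer seed; the fixture is byte-identical for a fixed seed.
#' @param n_records Records per window.
#' @param composition Named list: one named numeric vector of category
#'   fractions (summing to 1) per window start year, e.g.
#'   `list("2000" = c(MR = 0.5, MAD = 0.5))`.
#' @param window_years Window width in years.
#' @param straddle_fraction Fraction of records whose release date is pushed
#'   past the window end (they then bin nowhere).
#' @return A `survey_records` data frame.
#' @export
generate_survey_fixture <- function(seed, n_records, composition,
                                    window_years = 5L, straddle_fraction = 0) {
  if (straddle_fraction < 0 || straddle_fraction > 1) {
    stop_mrellg("straddle_fraction must lie in [0, 1]")
  }
  with_seed(seed, {
    rows <- list()
    serial <- 0L
    for (wstart in names(composition)) {
      frac <- composition[[wstart]]
      if (abs(sum(frac) - 1) > 1e-9) {
        stop_mrellg("composition fractions for window ", wstart, " must sum to 1")
      }
      if (any(!names(frac) %in% names(.alias_pool))) {
        stop_mrellg("composition references unknown categories")
      }
      y0 <- as.integer(wstart)
      counts <- round(frac * n_records)
      # fix rounding drift deterministically on the largest class
      counts[which.max(counts)] <- counts[which.max(counts)] + n_records - sum(counts)
      for (cat_ in names(counts)) {
        for (i in seq_len(counts[[cat_]])) {
          serial <- serial + 1L
          straddle <- stats::runif(1) < straddle_fraction
          dep <- as.Date(sprintf("%d-01-01", y0)) +
            floor(stats::runif(1, 0, 365 * window_years - 30))
          rel <- if (straddle) {
            as.Date(sprintf("%d-01-01", y0 + window_years)) + floor(stats::runif(1, 0, 365))
          } else {
            end <- as.Date(sprintf("%d-12-31", y0 + window_years - 1L))
            dep + floor(stats::runif(1, 0, as.numeric(end - dep) + 1))
          }
          pool <- .alias_pool[[cat_]]
          rows[[serial]] <- data.frame(
            id = sprintf("X%04d", serial),
            deposition_date = format(dep), release_date = format(rel),
            entity_id = "1",
            method_text = pool[sample.int(length(pool), 1)],
            stringsAsFactors = FALSE)
        }
      }
    }
    structure(do.call(rbind, rows), class = c("survey_records", "data.frame"))
  })
}
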