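#' Load a preferred-term to system-organ-class map
#'
#' MedDRA assigns every preferred term (PT) a primary system organ class
#' (SOC). The full dictionary is licensed and cannot be redistributed, so
#' the map is supplied as a simple two-column delimited file (PT, SOC);
#' [fixture_pt_soc()] gives a small packaged map covering the cardiac SOC.
#' Lookup is case-insensitive (PTs are canonicalized with [canon_str()]).
#'
#' @param path Two-column delimited file; first column PT, second column SOC
#'   (header row required, any names).
#' @param delim Field delimiter (default tab).
#' @param version_label Free-text label for the dictionary version.
#' @return A `pt_soc_map`: tibble with columns `pt` (as given), `pt_canon`,
#'   `soc`, plus a `version_label` attribute.
#' @export
load_pt_soc_map <- function(path, delim = "\t", version_label = NULL) {
  if (!file.exists(path)) {
    stop("PT-SOC map file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) stop("PT-SOC map is empty: ", path, call. = FALSE)
  if (ncol(raw) < 2) stop("PT-SOC map must have two columns (PT, SOC)",
                          call. = FALSE)
  map <- tibble::tibble(pt = trimws(raw[[1]]), soc = trimws(raw[[2]]),
                        pt_canon = canon_str(raw[[1]]))
  map <- dplyr::distinct(map, .data$pt_canon, .data$soc, .keep_all = TRUE)
  dup <- map$pt_canon[duplicated(map$pt_canon)]
  if (length(dup)) {
    stop("conflicting SOC assignment for PT(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  structure(map[, c("pt", "pt_canon", "soc")],
            version_label = version_label %||% "unversioned",
            class = c("pt_soc_map", class(map)))
}

#' Look up the SOC of preferred terms
#'
#' @param pts Character vector of PTs (any case).
#' @param map A `pt_soc_map` from [load_pt_soc_map()].
#' @return Character vector of SOC names; `NA` for unmapped PTs.
#' @export
#' @examples
#' map <- fixture_pt_soc()
#' pt_soc(c("torsade de pointes", "Rash", "no such term"), map)
pt_soc <- function(pts, map) {
  stopifnot(inherits(map, "pt_soc_map"))
  map$soc[match(canon_str(pts), map$pt_canon)]
}

#' Restrict reaction-level records to one system organ class
#'
#' Keeps exactly the records whose PT maps to `soc_name` — the SOC
#' restriction step of the screening funnel (by default the cardiac-disorders
#' SOC). Unmapped PTs are excluded, not an error; their count is attached as
#' the `n_unmapped` attribute.
#'
#' @param reactions A tibble with a `pt` column (reaction records or case
#'   rows).
#' @param map A `pt_soc_map`.
#' @param soc_name Target SOC (default `"Cardiac disorders"`).
#' @return The filtered tibble, with attributes `n_unmapped` and `n_removed`.
#' @export
filter_cardiac <- function(reactions, map, soc_name = "Cardiac disorders") {
  stopifnot("pt" %in% names(reactions))
  soc <- pt_soc(reactions$pt, map)
  keep <- !is.na(soc) & soc == soc_name
  out <- reactions[keep, ]
  attr(out, "n_unmapped") <- sum(is.na(soc))
  attr(out, "n_removed") <- sum(!keep)
  out
}
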