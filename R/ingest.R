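#' Read survey or reach tables from delimited text
#'
#' Autodetects the delimiter from the file extension (`.csv` comma,
#' `.tsv`/`.txt` tab). A `date` column, if present, is parsed as `Date`.
#'
#' @param path Path to a delimited text file.
#' @return A tibble.
#' @export
read_table_auto <- function(path) {
  if (!file.exists(path)) {
    stopf("input file not found: %s", path, class = "oefish_input_error")
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- tibble::as_tibble(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, check.names = FALSE)
  )
  if ("date" %in% names(out)) {
    out$date <- as.Date(as.character(out$date))
  }
  out
}

species_columns <- function(surveys) {
  setdiff(names(surveys),
          c("site_id", "reach_id", "date", "method", "reach_length_m"))
}

new_filter_report <- function(stage, removed, retained, detail = list()) {
  structure(list(stage = stage, removed = removed, retained = retained,
                 detail = detail),
            class = "oe_filter_report")
}

#' @export
print.oe_filter_report <- function(x, ...) {
  cat(sprintf("<oe_filter_report: %s>\n", x$stage))
  for (nm in names(x$removed)) {
    cat(sprintf("  removed [%s]: %d\n", nm, x$removed[[nm]]))
  }
  cat(sprintf("  retained: %d\n", x$retained))
  invisible(x)
}

#' Filter survey records to the analysis set
#'
#' Retains only records sampled in or after 2000, during the summer window
#' (December through March inclusive), by electric fishing, over a reach of
#' at least 150 m (all boundaries inclusive). Where a site then has multiple
#' retained records, exactly one is kept, chosen uniformly at random with a
#' seed derived from the global seed and the site id — so the choice is
#' reproducible and independent of input row order. Records with unparseable
#' dates are dropped with their own reason code. The report accounts for
#' every removal.
#'
#' @param surveys Survey tibble: `site_id`, `reach_id`, `date`, `method`,
#'   `reach_length_m`, then one 0/1 column per species.
#' @param seed Integer seed for the duplicate-site draw.
#' @param min_year Earliest retained survey year.
#' @param months Retained calendar months.
#' @param min_length_m Minimum surveyed reach length (m), inclusive.
#' @param methods Retained sampling method labels.
#' @return A list: `surveys` (the retained records, one per site) and
#'   `report` (an `oe_filter_report` with per-rule removal counts).
#' @export
filter_surveys <- function(surveys, seed = 1, min_year = 2000,
                           months = c(12L, 1L, 2L, 3L), min_length_m = 150,
                           methods = "electric") {
  check_columns(surveys, c("site_id", "reach_id", "date", "method",
                           "reach_length_m"), "survey table")
  n0 <- nrow(surveys)
  date <- suppressWarnings(as.Date(as.character(surveys$date)))
  year <- as.integer(format(date, "%Y"))
  month <- as.integer(format(date, "%m"))

  reason <- rep(NA_character_, n0)
  mark <- function(cond, code) {
    cond <- !is.na(cond) & cond
    reason[is.na(reason) & cond] <<- code
  }
  mark(is.na(date), "bad_date")
  mark(year < min_year, "pre_2000")
  mark(!month %in% months, "off_season")
  mark(!surveys$method %in% methods, "non_electric")
  mark(surveys$reach_length_m < min_length_m, "short_reach")

  keep <- is.na(reason)
  kept <- surveys[keep, , drop = FALSE]

  # one record per site, chosen order-independently: records within a site
  # are put into a canonical order and the index drawn from a seed keyed by
  # (global seed, site id)
  pick <- kept |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::arrange(.data$site_id, .data$date, .data$reach_id,
                   .data$reach_length_m) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(.keep_row = {
      k <- dplyr::n()
      idx <- if (k == 1L) 1L else {
        with_seed(derive_seed(seed, paste0("site:", .data$site_id[1])),
                  sample.int(k, 1L))
      }
      .data$.row[order(.data$date, .data$reach_id,
                       .data$reach_length_m)][idx]
    }, .groups = "drop")

  keep_rows <- sort(pick$.keep_row)
  dedup_removed <- nrow(kept) - length(keep_rows)
  out <- kept[keep_rows, , drop = FALSE]

  removed <- table(factor(reason, levels = c("bad_date", "pre_2000",
                                             "off_season", "non_electric",
                                             "short_reach")))
  removed <- c(as.list(removed), list(duplicate_site = dedup_removed))
  report <- new_filter_report(
    "record_filters",
    removed = lapply(removed, as.integer),
    retained = nrow(out),
    detail = list(input = n0)
  )
  stopifnot(sum(unlist(report$removed)) + report$retained == n0)
  list(surveys = out, report = report)
}

#' Prevalence filter: species surveyed at enough sites
#'
#' Returns the species present at at least `min_sites` distinct sites
#' (inclusive). Counts sites, not records; the input is expected to already
#' hold one record per site.
#'
#' @param surveys Deduplicated survey tibble.
#' @param min_sites Minimum number of presence sites, inclusive.
#' @return A list: `species` (retained ids), `report`.
#' @export
prevalence_filter <- function(surveys, min_sites = 150) {
  sp <- species_columns(surveys)
  if (nrow(surveys) == 0L) {
    warn("prevalence_filter: empty record list; no species retained")
    return(list(species = character(),
                report = new_filter_report("prevalence",
                                           list(below_min_sites = length(sp)),
                                           0L)))
  }
  n_sites <- vapply(sp, function(s) {
    length(unique(surveys$site_id[surveys[[s]] == 1]))
  }, integer(1))
  kept <- sp[n_sites >= min_sites]
  list(
    species = kept,
    report = new_filter_report("prevalence",
                               list(below_min_sites = length(sp) - length(kept)),
                               length(kept),
                               detail = list(presence_sites = n_sites))
  )
}

#' River-class filter: classes with enough survey sites
#'
#' Returns the river classes containing at least `min_sites` survey sites
#' (inclusive). All model fitting and all downstream prediction are
#' restricted to reaches of retained classes, to limit extrapolation.
#'
#' @param surveys Deduplicated survey tibble.
#' @param reaches Reach table with `reach_id` and `river_class`.
#' @param min_sites Minimum survey sites per class, inclusive.
#' @return A list: `classes` (retained labels), `report`.
#' @export
class_filter <- function(surveys, reaches, min_sites = 1000) {
  check_columns(reaches, c("reach_id", "river_class"), "reach table")
  unknown <- setdiff(surveys$reach_id, reaches$reach_id)
  if (length(unknown)) {
    stopf("survey records reference unknown reaches: %s",
          paste(head(unknown, 3), collapse = ", "),
          class = "oefish_consistency_error")
  }
  cls <- reaches$river_class[match(surveys$reach_id, reaches$reach_id)]
  counts <- table(cls)
  kept <- names(counts)[counts >= min_sites]
  list(
    classes = kept,
    report = new_filter_report("river_class",
                               list(below_min_sites = length(counts) - length(kept)),
                               length(kept),
                               detail = list(sites_per_class = as.list(counts)))
  )
}

#' Pairwise collinearity screen of reach covariates
#'
#' Pearson correlation and two-sided p-value for every pair of numeric
#' covariates, as a symmetric report (diagonal r = 1). Zero-variance
#' covariates yield flagged `NA` correlations rather than errors. The screen
#' is a report only — no variables are removed automatically.
#'
#' @param reaches Reach table; non-numeric columns and `reach_id` ignored.
#' @return A tibble of class `oe_collinearity`: `var1`, `var2`, `r`, `p`,
#'   `n`, `flag` — one row per unordered pair plus the diagonal.
#' @export
collinearity_screen <- function(reaches) {
  num <- reaches[vapply(reaches, is.numeric, TRUE)]
  vars <- names(num)
  if (length(vars) < 2) {
    stopf("need at least two numeric covariates", class = "oefish_schema_error")
  }
  pairs <- tidyr::expand_grid(var1 = vars, var2 = vars) |>
    dplyr::filter(match(.data$var1, vars) <= match(.data$var2, vars))
  res <- purrr::pmap_dfr(pairs, function(var1, var2) {
    x <- num[[var1]]; y <- num[[var2]]
    ok <- complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (var1 == var2) {
      flag <- if (sd(x) == 0) "zero_variance" else "ok"
      return(tibble::tibble(var1, var2,
                            r = if (flag == "ok") 1 else NA_real_,
                            p = NA_real_, n = length(x), flag = flag))
    }
    if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) {
      return(tibble::tibble(var1, var2, r = NA_real_, p = NA_real_,
                            n = length(x), flag = "zero_variance"))
    }
    ct <- cor.test(x, y, method = "pearson")
    tibble::tibble(var1, var2, r = unname(ct$estimate), p = ct$p.value,
                   n = length(x), flag = "ok")
  })
  class(res) <- c("oe_collinearity", class(res))
  res
}

#' Spread a collinearity report to matrices
#'
#' @param screen Result of [collinearity_screen()].
#' @return A list with symmetric matrices `r` and `p`.
#' @export
collinearity_matrices <- function(screen) {
  vars <- unique(c(screen$var1, screen$var2))
  r <- p <- matrix(NA_real_, length(vars), length(vars),
                   dimnames = list(vars, vars))
  for (i in seq_len(nrow(screen))) {
    r[screen$var1[i], screen$var2[i]] <- r[screen$var2[i], screen$var1[i]] <-
      screen$r[i]
    p[screen$var1[i], screen$var2[i]] <- p[screen$var2[i], screen$var1[i]] <-
      screen$p[i]
  }
  list(r = r, p = p)
}
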