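#' Read a table of p-value pairs
#'
#' Reads delimited text (TSV or CSV, auto-detected from the header line)
#' with required columns `p` and `q` and optional `id` and `fold` columns.
#' Rows with missing `p` or `q` are dropped with a message; zero p-values
#' are clamped by [as_pq_data()] with a warning.
#'
#' @param path Path to a delimited text file with a header.
#' @return A validated tibble (see [as_pq_data()]).
#' @export
read_pq_table <- function(path) {
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  missing_cols <- setdiff(c("p", "q"), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Input file is missing required column(s): ",
                 paste0("`", missing_cols, "`", collapse = ", "), "."))
  }
  drop <- is.na(raw$p) | is.na(raw$q)
  if (all(drop)) abort("All rows have missing `p` or `q`.")
  if (any(drop)) {
    inform(paste0("Dropped ", sum(drop), " row(s) with missing `p` or `q`."))
    raw <- raw[!drop, ]
  }
  as_pq_data(raw)
}

#' Write v-value results to delimited text
#'
#' Writes a fixed-order table (`id`, `p`, `q`, `v`, `c`, `rejected`,
#'  `mode`, `alpha`) that round-trips through [read_pq_table()] without
#' loss at double precision.
#'
#' @param path Output path.
#' @param vset A `cfdr_vvalues` tibble from [cfdr_vvalues()].
#' @param rejected Logical rejection vector aligned with `vset` (e.g. from
#'   [bh_reject()]).
#' @param alpha The level used for `rejected` (recorded in the output).
#' @return `path`, invisibly.
#' @export
write_vvalues <- function(path, vset, rejected, alpha = NA_real_) {
  if (nrow(vset) != length(rejected)) {
    abort("`rejected` must align with `vset`.")
  }
  out <- tibble(
    id = vset$id, p = vset$p, q = vset$q, v = vset$v, c = vset$c,
    rejected = rejected,
    mode = attr(vset, "mode") %||% NA_character_,
    alpha = alpha
  )
  readr::write_tsv(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
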