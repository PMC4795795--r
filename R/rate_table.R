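## Long-format rate tables: the package's exchange format for simulated or
## externally supplied unit-by-condition responses.

.rate_table_cols <- c("unit_id", "node", "u", "v", "gain_sign",
                      "E", "H", "T", "t", "rate")

#' Assemble a long-format rate table
#'
#' One row per unit x condition: unit descriptors, task positions, the
#' normalized observation time and the (possibly noisy) rate.
#'
#' @param units unit table.
#' @param cond condition table aligned with the columns of `rates`.
#' @param t scalar normalized time of observation.
#' @param rates units x conditions rate matrix.
#' @return a `data.frame` with the documented column schema.
#' @export
rate_table <- function(units, cond, t, rates) {
  stopifnot(nrow(rates) == nrow(units), ncol(rates) == nrow(cond))
  n_u <- nrow(units); n_c <- nrow(cond)
  data.frame(unit_id = rep(units$unit_id, times = n_c),
             node = rep(units$node, times = n_c),
             u = rep(units$u, times = n_c),
             v = rep(units$v, times = n_c),
             gain_sign = rep(units$gain_sign, times = n_c),
             E = rep(cond$E, each = n_u),
             H = rep(cond$H, each = n_u),
             T = rep(cond$T, each = n_u),
             t = t,
             rate = as.vector(rates),
             stringsAsFactors = FALSE)
}

#' Write a rate table to CSV
#' @param tbl a rate table (see [rate_table()]).
#' @param path output file path.
#' @export
write_rate_table <- function(tbl, path) {
  stopifnot(all(.rate_table_cols %in% names(tbl)))
  utils::write.csv(tbl[, .rate_table_cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a rate table from CSV
#'
#' Validates the column schema; a missing column is an error naming it,
#' extra columns are dropped with a warning. This is the entry point of the
#' analysis-only path: screened fits and classifications can be computed on
#' externally supplied responses via [rate_table_matrices()].
#'
#' @param path CSV file path.
#' @return a `data.frame` in the documented schema.
#' @export
load_rate_table <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.rate_table_cols, names(tbl))
  if (length(missing)) {
    stop("rate table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(tbl), .rate_table_cols)
  if (length(extra)) {
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "))
  }
  tbl[, .rate_table_cols]
}

#' Split a rate table into units, conditions and a rate matrix
#'
#' @param tbl a rate table in the documented schema (single time point).
#' @return list with `units`, `cond`, `t` and the units x conditions
#'   matrix `rates`.
#' @export
rate_table_matrices <- function(tbl) {
  stopifnot(all(.rate_table_cols %in% names(tbl)))
  if (length(unique(tbl$t)) != 1L) {
    stop("expected a single observation time per table", call. = FALSE)
  }
  u_first <- !duplicated(tbl$unit_id)
  units <- data.frame(unit_id = tbl$unit_id[u_first],
                      node = tbl$node[u_first], u = tbl$u[u_first],
                      v = tbl$v[u_first], gain_sign = tbl$gain_sign[u_first],
                      stringsAsFactors = FALSE)
  key <- paste(tbl$E, tbl$H, tbl$T)
  c_first <- !duplicated(key)
  cond <- task_conditions(tbl$E[c_first], tbl$H[c_first], tbl$T[c_first])
  rates <- matrix(NA_real_, nrow(units), nrow(cond),
                  dimnames = list(units$unit_id, NULL))
  ui <- match(tbl$unit_id, units$unit_id)
  ci <- match(key, key[c_first])
  rates[cbind(ui, ci)] <- tbl$rate
  list(units = units, cond = cond, t = tbl$t[1], rates = rates)
}
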