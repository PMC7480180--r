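# Builders for small deterministic panels used across the tests.

# Rectangular panel with constant outcome rates and covariates; rates can be
# overridden per practice via the `rates` list (id -> named outcome rates).
constant_panel <- function(ids, n_months = 24, list_size = 5000,
                           rates = list(),
                           base = c(ed_rate = 2.5, adm_rate = 1.0,
                                    readm_rate = 0.12)) {
  if (length(list_size) == 1) list_size <- rep(list_size, length(ids))
  rows <- lapply(seq_along(ids), function(i) {
    r <- base
    if (!is.null(rates[[ids[i]]])) r[names(rates[[ids[i]]])] <- rates[[ids[i]]]
    df <- data.frame(practice_id = ids[i], month_index = seq_len(n_months),
                     list_size = list_size[i],
                     ed_rate = r[["ed_rate"]], adm_rate = r[["adm_rate"]],
                     readm_rate = r[["readm_rate"]], em_los = 5,
                     stringsAsFactors = FALSE)
    for (cv in scmeval:::COVARIATE_COLS) df[[cv]] <- 10 + i
    df
  })
  do.call(rbind, rows)
}

# Panel whose outcome paths are supplied directly: `paths` is a named list
# id -> list(ed_rate =, adm_rate =, readm_rate =) of length-n_months vectors
# (missing outcomes fall back to a constant).
path_panel <- function(paths, n_months, list_size = 5000, covs = NULL) {
  ids <- names(paths)
  rows <- lapply(seq_along(ids), function(i) {
    p <- paths[[ids[i]]]
    df <- data.frame(practice_id = ids[i], month_index = seq_len(n_months),
                     list_size = list_size,
                     ed_rate = p$ed_rate %||% rep(2.5, n_months),
                     adm_rate = p$adm_rate %||% rep(1.0, n_months),
                     readm_rate = p$readm_rate %||% rep(0.12, n_months),
                     em_los = 5, stringsAsFactors = FALSE)
    for (cv in scmeval:::COVARIATE_COLS)
      df[[cv]] <- if (!is.null(covs)) covs[[ids[i]]][[cv]] %||% 10 else 10
    df
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

simple_schedule <- function(ids, join, exit = NA_integer_) {
  stats::setNames(lapply(seq_along(ids), function(i)
    list(join_month = join[min(i, length(join))], exit_month = exit)), ids)
}

# Donor pool object without list-size screening, for direct SCM tests.
manual_pool <- function(treated_id, donor_ids) {
  structure(list(treated_id = treated_id, donor_ids = donor_ids,
                 constraint_log = NULL), class = "donor_pool")
}

# Exhaustive simplex grid over donor weights (2 or 3 donors), returning the
# minimum of `objfun` over the grid. Independent oracle for the QP and for
# the attainable outcome MSPE of the nested fit.
grid_min <- function(objfun, n_donors, step = 0.01) {
  stopifnot(n_donors %in% 2:3)
  g <- seq(0, 1, by = step)
  best <- Inf
  if (n_donors == 2) {
    for (a in g) best <- min(best, objfun(c(a, 1 - a)))
  } else {
    for (a in g) for (b in seq(0, 1 - a, by = step))
      best <- min(best, objfun(c(a, b, 1 - a - b)))
  }
  best
}
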