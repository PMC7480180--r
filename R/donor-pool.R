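#' Construct a treated practice's donor pool
#'
#' Donors are all practices that (a) are not in the intervention schedule and
#' (b) have a registered list size within `tolerance` (default +/-20%,
#' boundary inclusive) of the treated practice's list size, both measured in
#' the month before the treated practice joins. An optional categorical
#' filter restricts donors to those sharing the treated practice's value of
#' a grouping column (a stand-in for geographic referral-area restrictions).
#'
#' Every candidate's inclusion or exclusion (with reason) is recorded in the
#' `constraint_log`.
#'
#' @param panel a monthly panel data.frame.
#' @param schedule intervention schedule (named list, id -> join/exit).
#' @param treated_id id of the treated practice; must be in `schedule`.
#' @param tolerance relative half-width of the list-size band, in (0, 1).
#' @param group_col optional panel column name for the categorical filter.
#' @return an object of class `donor_pool`: list with `treated_id`,
#'   `donor_ids`, `ref_month`, `treated_list_size` and `constraint_log`
#'   (data.frame of candidate_id, list_size, included, reason).
#' @export
build_donor_pool <- function(panel, schedule, treated_id,
                             tolerance = 0.20, group_col = NULL) {
  if (!treated_id %in% names(schedule))
    stopf("practice %s is not in the intervention schedule", treated_id)
  if (tolerance <= 0 || tolerance >= 1)
    stopf("tolerance must be in (0, 1)")
  join <- schedule[[treated_id]]$join_month
  ref_month <- join - 1L
  at_ref <- panel[panel$month_index == ref_month, , drop = FALSE]
  if (!treated_id %in% at_ref$practice_id)
    stopf("treated practice %s has no row at month %d", treated_id, ref_month)
  L <- at_ref$list_size[at_ref$practice_id == treated_id]
  band <- c((1 - tolerance) * L, (1 + tolerance) * L)

  cand <- at_ref[at_ref$practice_id != treated_id, , drop = FALSE]
  treated_set <- names(schedule)
  reason <- rep("", nrow(cand))
  included <- rep(TRUE, nrow(cand))

  is_treated <- cand$practice_id %in% treated_set
  included[is_treated] <- FALSE
  reason[is_treated] <- "treated"

  off_band <- cand$list_size < band[1] | cand$list_size > band[2]
  drop_ls <- !is_treated & off_band
  included[drop_ls] <- FALSE
  reason[drop_ls] <- "list_size"

  if (!is.null(group_col)) {
    if (!group_col %in% names(panel))
      stopf("group column '%s' not in panel", group_col)
    g0 <- at_ref[[group_col]][at_ref$practice_id == treated_id]
    off_g <- cand[[group_col]] != g0
    drop_g <- included & off_g
    included[drop_g] <- FALSE
    reason[drop_g] <- "group"
  }

  log <- data.frame(candidate_id = cand$practice_id,
                    list_size = cand$list_size,
                    included = included, reason = reason,
                    stringsAsFactors = FALSE)
  donor_ids <- sort(cand$practice_id[included])
  if (!length(donor_ids))
    stopf(paste0("empty donor pool for %s: no practice within %.0f%% of list",
                 " size %d at month %d; consider increasing the tolerance"),
          treated_id, 100 * tolerance, L, ref_month)
  structure(list(treated_id = treated_id, donor_ids = donor_ids,
                 ref_month = ref_month, treated_list_size = L,
                 constraint_log = log),
            class = "donor_pool")
}

#' @export
print.donor_pool <- function(x, ...) {
  cat(sprintf("Donor pool for %s: %d donors (of %d candidates), list size %d +/- band at month %d\n",
              x$treated_id, length(x$donor_ids), nrow(x$constraint_log),
              x$treated_list_size, x$ref_month))
  excl <- x$constraint_log[!x$constraint_log$included, ]
  if (nrow(excl)) {
    tab <- table(excl$reason)
    cat("  excluded:", paste(sprintf("%s (%d)", names(tab), tab),
                             collapse = ", "), "\n")
  }
  invisible(x)
}
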