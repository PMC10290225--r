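# The effect journal: every observable consequence of a run (log lines,
# filesystem mutations, warnings, early exit) is appended as one record.
# Workers own private journals; merge happens once, at run end, and rows
# are canonically ordered by (walk_index, action_seq) so the finalized
# journal is independent of scheduling.

journal_add <- function(ctx, kind, path, detail = "") {
  ctx$jn <- ctx$jn + 1L
  ctx$journal[[ctx$jn]] <- list(
    walk_index = ctx$walk_index,
    action_seq = ctx$action_seq,
    path = path,
    rule_scope = ctx$current_scope,
    effect_kind = kind,
    detail = detail
  )
  ctx$action_seq <- ctx$action_seq + 1L
  invisible(NULL)
}

journal_df <- function(rows) {
  if (length(rows) == 0L) {
    return(data.frame(walk_index = integer(0), action_seq = integer(0),
                      path = character(0), rule_scope = character(0),
                      effect_kind = character(0), detail = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    walk_index = vapply(rows, `[[`, 0L, "walk_index"),
    action_seq = vapply(rows, `[[`, 0L, "action_seq"),
    path = vapply(rows, `[[`, "", "path"),
    rule_scope = vapply(rows, `[[`, "", "rule_scope"),
    effect_kind = vapply(rows, `[[`, "", "effect_kind"),
    detail = vapply(rows, `[[`, "", "detail"),
    stringsAsFactors = FALSE
  )
}

# Canonical order: serial walk position, then per-node action sequence.
canonicalize_journal <- function(df) {
  df[order(df$walk_index, df$action_seq), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}
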