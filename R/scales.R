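#' Depression rating-scale definitions
#'
#' Returns the item structure of the two depression severity instruments the
#' package works with: the 17-item Hamilton Depression Rating Scale (HAMD-17,
#' nine items scored 0-4 and eight scored 0-2, total range 0-52) and the
#' 10-item Montgomery-Asberg Depression Rating Scale (MADRS, every item
#' scored 0-6, total range 0-60). The total score is the sum of the items.
#'
#' @param name `"HAMD17"` or `"MADRS"`.
#' @return an object of class `scale_definition`: a list with elements
#'   `name`, `n_items`, `item_max` (per-item maximum scores) and `max_total`.
#' @examples
#' scale_definition("MADRS")$max_total  # 60
#' @export
scale_definition <- function(name = c("HAMD17", "MADRS")) {
  name <- match.arg(name)
  item_max <- switch(name,
    # standard HAMD-17 item ceilings: items 4-6, 12-14, 16, 17 are 0-2
    HAMD17 = c(4, 4, 4, 2, 2, 2, 4, 4, 4, 4, 4, 2, 2, 2, 4, 2, 2),
    MADRS = rep(6L, 10)
  )
  structure(
    list(
      name = name,
      n_items = length(item_max),
      item_max = as.integer(item_max),
      max_total = as.integer(sum(item_max))
    ),
    class = "scale_definition"
  )
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf(
    "<scale_definition> %s: %d items, total score 0-%d\n",
    x$name, x$n_items, x$max_total
  ))
  invisible(x)
}

item_columns <- function(scale) {
  sprintf("item_%02d", seq_len(scale$n_items))
}

#' Typical trial-entry severity for a scale
#'
#' Mean total score used by the simulator to seed screening severity:
#' moderate-to-severe depression entry criteria put typical enrolment totals
#' near 22 on the HAMD-17 and 30 on the MADRS.
#'
#' @param scale a [scale_definition()].
#' @return numeric mean entry total score.
#' @keywords internal
default_entry_severity <- function(scale) {
  switch(scale$name, HAMD17 = 22, MADRS = 30)
}
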