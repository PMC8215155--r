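#' Tidy ribotunnel objects into tibbles
#'
#' `tidy()` returns the row-per-observation view of an object: the contact
#' list of a `native_model`, the per-rotation volumes of a `cavity_map`,
#' the event log of a `cg_trajectory`.
#'
#' @param x a `native_model`, `cavity_map` or `cg_trajectory`.
#' @param ... unused.
#' @return a tibble.
#' @name tidy-ribotunnel
NULL

#' One-row summaries of ribotunnel objects
#'
#' `glance()` returns a one-row tibble of headline numbers: residue and
#' contact counts for a `native_model`, volume and surface-to-volume for a
#' `cavity_map`, end time and folding/escape times for a `cg_trajectory`.
#'
#' @param x a `native_model`, `cavity_map` or `cg_trajectory`.
#' @param ... unused.
#' @return a one-row tibble.
#' @name glance-ribotunnel
NULL
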