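# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a similarity score
#' @param x A `similarity_score`.
#' @param ... Unused.
#' @return One-row tibble: `reference`, `r`, `n_pairs`.
#' @export
tidy.similarity_score <- function(x, ...) {
  tibble(reference = x$reference_id %||% NA_character_,
         r = x$r, n_pairs = x$n_pairs)
}

#' @rdname tidy.similarity_score
#' @export
glance.similarity_score <- function(x, ...) tidy.similarity_score(x)

#' Tidy a structure label
#' @param x A `structure_label`.
#' @param ... Unused.
#' @return Per-reference similarity tibble with the assigned class.
#' @export
tidy.structure_label <- function(x, ...) {
  if (is.null(x$scores)) {
    return(tibble(reference = character(0), r = numeric(0),
                  class = character(0)))
  }
  out <- x$scores
  out$class <- x$class
  out
}

#' @rdname tidy.structure_label
#' @param ... Unused.
#' @export
glance.structure_label <- function(x, ...) {
  tibble(class = x$class, in_register = x$in_register,
         best_r = if (is.null(x$scores)) NA_real_ else max(x$scores$r),
         energy = x$energy %||% NA_real_,
         largest_cluster = x$cluster_sizes[1])
}

#' Tidy a simulation run
#' @param x A `dmd_run`.
#' @param ... Unused.
#' @return The observable series as a tibble.
#' @export
tidy.dmd_run <- function(x, ...) x$observables

#' @rdname tidy.dmd_run
#' @param ... Unused.
#' @export
glance.dmd_run <- function(x, ...) {
  o <- x$observables
  tibble(n_chains = x$config$n_chains,
         budget = x$config$budget,
         segments = nrow(x$segments),
         final_energy = if (nrow(o)) o$pe[nrow(o)] else NA_real_,
         final_n_hb = if (nrow(o)) o$n_hb[nrow(o)] else NA_real_,
         final_cluster = if (nrow(o)) o$largest_cluster[nrow(o)] else
           NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
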