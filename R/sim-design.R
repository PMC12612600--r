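#' Simulate a clonal seed orchard planting design
#'
#' Allocates each site's ramets to clones as evenly as possible (so a few
#' clones receive one extra ramet, as when "up to k ramets per clone" are
#' sampled), then scatters ramets over the site's row/column grid at random
#' distinct cells. Unoccupied cells play the role of mortality gaps: spatial
#' correlation downstream uses grid distances of the occupied cells.
#'
#' @param config a [sim_config()].
#' @return an `orchard_design`: data.frame with columns `site`, `row`, `col`,
#'   `clone`, `population`, one row per ramet.
#' @export
simulate_orchard_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  populations <- rep_len(seq_len(config$n_populations), config$n_clones)
  out <- vector("list", config$n_sites)
  with_seed(derive_seed(config$seed, 1L), {
    for (s in seq_len(config$n_sites)) {
      clones <- config$clones_per_site[[s]]
      n_ram <- config$ramets_per_site[s]
      n_cells <- config$grid_rows[s] * config$grid_cols[s]
      if (n_cells < n_ram)
        stop_bad_arg(sprintf("site %d: grid capacity %d < %d ramets",
                             s, n_cells, n_ram))
      # even allocation: repeat the clone list until n_ram reached
      clone_of_ramet <- rep_len(sample(clones), n_ram)
      cells <- sample.int(n_cells, n_ram)
      out[[s]] <- data.frame(
        site = s,
        row = ((cells - 1L) %% config$grid_rows[s]) + 1L,
        col = ((cells - 1L) %/% config$grid_rows[s]) + 1L,
        clone = clone_of_ramet,
        population = populations[clone_of_ramet])
    }
  })
  design <- do.call(rbind, out)
  design$ramet <- sprintf("S%d_R%02d_C%02d", design$site, design$row, design$col)
  rownames(design) <- NULL
  class(design) <- c("orchard_design", "data.frame")
  validate_design(design)
  design
}

validate_design <- function(design) {
  need <- c("site", "row", "col", "clone")
  if (!all(need %in% names(design)))
    stop_bad_arg("design needs columns: ", paste(need, collapse = ", "))
  key <- paste(design$site, design$row, design$col)
  if (anyDuplicated(key))
    stop_bad_arg("duplicate (site, row, col) grid cells in design")
  invisible(design)
}
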