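# Shared fixtures and independent oracles, built in code at test time.

# Independent connected-component oracle: BFS flood fill over an explicit
# queue, 8-connectivity, pure R. Returns the bounding box (row0, col0,
# height, width; 0-based) of the largest above-threshold component.
oracle_largest_component_box <- function(image, threshold = 5) {
  fg <- image > threshold
  h <- nrow(fg); w <- ncol(fg)
  seen <- matrix(FALSE, h, w)
  best <- NULL; best_area <- -1L
  stack <- integer(h * w)
  cells <- integer(h * w)
  for (start in which(fg)) {
    if (seen[start]) next
    top <- 1L
    stack[1L] <- start
    seen[start] <- TRUE
    n_cells <- 0L
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      n_cells <- n_cells + 1L
      cells[n_cells] <- cur
      ci <- (cur - 1L) %% h + 1L         # row
      cj <- (cur - 1L) %/% h + 1L        # col
      for (di in -1:1) for (dj in -1:1) {
        ii <- ci + di; jj <- cj + dj
        if (ii < 1L || jj < 1L || ii > h || jj > w) next
        nb <- (jj - 1L) * h + ii
        if (fg[nb] && !seen[nb]) {
          seen[nb] <- TRUE
          top <- top + 1L
          stack[top] <- nb
        }
      }
    }
    comp <- cells[seq_len(n_cells)]
    rows <- (comp - 1L) %% h + 1L
    cols <- (comp - 1L) %/% h + 1L
    box <- c(row0 = min(rows) - 1L, col0 = min(cols) - 1L,
             height = diff(range(rows)) + 1L, width = diff(range(cols)) + 1L)
    area <- n_cells
    if (area > best_area ||
        (area == best_area && (box["row0"] < best["row0"] ||
          (box["row0"] == best["row0"] && box["col0"] < best["col0"])))) {
      best_area <- area; best <- box
    }
  }
  best
}

# Small in-memory synthetic manifest shared across tests.
tiny_manifest <- function(n_per_sex = 4, frames = c(3L, 3L), sex_effect = 1,
                          seed = 101, defect_rate = 0, ...) {
  generate_dataset(n_per_sex = n_per_sex, frames_range = frames,
                   defect_rate = defect_rate,
                   params = population_params(sex_effect = sex_effect, ...),
                   seed = seed)
}

gaussian_blob <- function(n, center, sd = 1, seed = NULL) {
  draw <- function() sweep(matrix(rnorm(n * length(center), 0, sd), n,
                                  length(center)), 2, center, "+")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
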