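# Shared helpers: small lattices and hand-placed cell configurations.

smallParams <- function(...) {
  tumorParams(dims = c(20L, 20L, 20L), ...)
}

# a single cell of the given type at the lattice center
oneCellSim <- function(params = smallParams(), lineage = "progenitor",
                       ccr5 = "low", state = "proliferative",
                       divisions = 0L, at = params@dims %/% 2L) {
  simFromCells(
    data.frame(i = at[1], j = at[2], k = at[3], lineage = lineage,
               ccr5 = ccr5, state = state, divisions = divisions),
    params
  )
}

# fully enclose the cell at `center` with its 26 Moore neighbors
enclosedSim <- function(params = smallParams(), center = c(10L, 10L, 10L),
                        skip = 0L) {
  nb <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nb <- nb[rowSums(nb == 0L) < 3L, , drop = FALSE]
  if (skip > 0L) nb <- nb[-seq_len(skip), , drop = FALSE]
  coords <- rbind(center, sweep(nb, 2, center, "+"))
  simFromCells(
    data.frame(i = coords[, 1], j = coords[, 2], k = coords[, 3]),
    params
  )
}

# binomial tolerance: 3 standard errors of a proportion
binomTol <- function(p, n) 3 * sqrt(p * (1 - p) / n)
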