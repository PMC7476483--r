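# Explicit-hydrogen molecular graph, extracted from an OpenBabel SDF block
# parsed by ChemmineR. Used by the surrogate predictor to classify proton
# environments.

mol_graph <- function(smiles) {
  sdf_txt <- ob_convert("SMI", "SDF", smiles,
                        options = data.frame(names = c("h", "gen2D"),
                                             args = c("", "")))
  if (!nzchar(trimws(sdf_txt))) stop_invalid_molecule(smiles)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(sdf_txt, tf)
  sdf <- ChemmineR::read.SDFset(tf)[[1]]
  elements <- sub("_\\d+$", "", rownames(ChemmineR::atomblock(sdf)))
  bb <- ChemmineR::bondblock(sdf)
  n <- length(elements)
  from <- as.integer(bb[, 1]); to <- as.integer(bb[, 2])
  order <- as.integer(bb[, 3])
  adj <- vector("list", n)
  bond_order <- vector("list", n)
  for (k in seq_along(from)) {
    i <- from[k]; j <- to[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    bond_order[[i]] <- c(bond_order[[i]], order[k])
    bond_order[[j]] <- c(bond_order[[j]], order[k])
  }
  # ring membership = 2-core: iteratively strip degree-<=1 vertices
  deg <- vapply(adj, length, integer(1))
  alive <- rep(TRUE, n)
  repeat {
    drop <- which(alive & deg <= 1L)
    if (length(drop) == 0L) break
    alive[drop] <- FALSE
    for (v in drop) for (u in adj[[v]]) if (alive[u]) deg[u] <- deg[u] - 1L
  }
  list(elements = elements, adj = adj, bond_order = bond_order,
       in_ring = alive, n = n)
}

graph_neighbors <- function(g, i) g$adj[[i]]

graph_order <- function(g, i, j) {
  g$bond_order[[i]][match(j, g$adj[[i]])]
}
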