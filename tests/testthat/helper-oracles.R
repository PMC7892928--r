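# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# central finite differences
num_grad <- function(f, p, eps = 1e-6) {
  g <- p * 0
  for (i in seq_along(p)) {
    pp <- p; pp[i] <- pp[i] + eps
    pm <- p; pm[i] <- pm[i] - eps
    g[i] <- (f(pp) - f(pm)) / (2 * eps)
  }
  g
}

# brute-force voxelwise TP/FP/FN counter (explicit loop)
oracle_counts <- function(p, g) {
  tp <- fp <- fn <- 0L
  pv <- as.integer(p)
  gv <- as.integer(g)
  for (i in seq_along(pv)) {
    if (pv[i] == 1L && gv[i] == 1L) tp <- tp + 1L
    else if (pv[i] == 1L) fp <- fp + 1L
    else if (gv[i] == 1L) fn <- fn + 1L
  }
  c(tp = tp, fp = fp, fn = fn)
}

oracle_dice <- function(p, g) {
  n <- oracle_counts(p, g)
  if (sum(p) == 0 && sum(g) == 0) return(1)
  2 * n[["tp"]] / (2 * n[["tp"]] + n[["fp"]] + n[["fn"]])
}

# keep-largest oracle: label components with igraph over the 26-adjacency
# graph of foreground voxels, rank by (size desc, first scan-order voxel asc)
oracle_keep_largest <- function(mask, max_components = 2L) {
  dm <- dim(mask)
  fg <- which(mask == 1L)
  if (length(fg) == 0L) return(mask * 0L)
  coord <- arrayInd(fg, dm)
  idx_of <- new.env(hash = TRUE)
  for (i in seq_along(fg)) assign(as.character(fg[i]), i, envir = idx_of)
  edges <- integer(0)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (i in seq_along(fg)) {
    for (r in seq_len(nrow(offs))) {
      nb <- coord[i, ] + offs[r, ]
      if (any(nb < 1) || any(nb > dm)) next
      flat <- nb[1] + dm[1] * (nb[2] - 1) + dm[1] * dm[2] * (nb[3] - 1)
      j <- mget(as.character(flat), envir = idx_of, ifnotfound = list(NULL))[[1]]
      if (!is.null(j) && j > i) edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize
  firsts <- vapply(seq_along(sizes), function(k) min(fg[comp$membership == k]),
                   numeric(1))
  keep <- order(-sizes, firsts)[seq_len(min(max_components, length(sizes)))]
  out <- mask * 0L
  out[fg[comp$membership %in% keep]] <- 1L
  out
}

# random binary mask with k blob components (blobs may merge)
random_blob_mask <- function(dm = c(12L, 12L, 12L), k = 3L) {
  m <- array(0L, dm)
  for (b in seq_len(k)) {
    c0 <- sapply(dm, function(n) sample.int(n, 1))
    r <- sample(1:2, 3, replace = TRUE)
    lo <- pmax(c0 - r, 1)
    hi <- pmin(c0 + r, dm)
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1L
  }
  m
}

# small normalized phantom subject shared by several files
tiny_subject <- function(seed = 5) {
  s <- generate_subject(phantom_spec(seed = seed))
  list(image = minmax_normalize(s$image), label = s$label)
}
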