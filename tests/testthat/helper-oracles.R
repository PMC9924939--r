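# Independent oracles used across the suite. Each one is a deliberately
# naive reimplementation (double loops, exhaustive scans) kept separate
# from the package's code paths.

# O(n^2) colocalization count: reference points with >= 1 target
# strictly within r
brute_force_coloc <- function(ref, tgt, r) {
  count <- 0L
  for (i in seq_len(nrow(ref))) {
    hit <- FALSE
    for (j in seq_len(nrow(tgt))) {
      d2 <- sum((ref[i, ] - tgt[j, ])^2)
      if (d2 < r^2) {
        hit <- TRUE
        break
      }
    }
    if (hit) count <- count + 1L
  }
  count
}

# O(N * 26) local-maxima scan (candidate voxels only; plateaus not
# collapsed — the caller compares against the plateau-voxel union)
oracle_maxima_mask <- function(resp) {
  dm <- dim(resp)
  mask <- array(FALSE, dm)
  for (z in seq_len(dm[1])) for (y in seq_len(dm[2])) for (x in seq_len(dm[3])) {
    ok <- TRUE
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      zz <- z + dz; yy <- y + dy; xx <- x + dx
      if (zz < 1 || zz > dm[1] || yy < 1 || yy > dm[2] ||
          xx < 1 || xx > dm[3]) next
      if (resp[zz, yy, xx] > resp[z, y, x]) ok <- FALSE
    }
    mask[z, y, x] <- ok
  }
  mask
}

# single-linkage components at distance <= r via an independent
# union-find over the full O(n^2) adjacency
oracle_single_linkage <- function(coords, r) {
  n <- nrow(coords)
  parent <- seq_len(n)
  findp <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (sum((coords[i, ] - coords[j, ])^2) <= r^2) {
        ri <- findp(i); rj <- findp(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), findp, integer(1))
  match(roots, unique(roots))
}

# exhaustive 256-bin Otsu: try every cut, compute class stats directly
# from the binned values
oracle_otsu <- function(values, n_bins = 256L) {
  r <- range(values)
  width <- (r[2] - r[1]) / n_bins
  bin <- pmin(floor((values - r[1]) / width) + 1L, n_bins)
  mids <- r[1] + (seq_len(n_bins) - 0.5) * width
  v <- mids[bin] # bin-midpoint representation, as a histogram method sees it
  best <- -Inf
  best_k <- NA_integer_
  for (k in 1:(n_bins - 1L)) {
    lo <- v[bin <= k]
    hi <- v[bin > k]
    if (length(lo) == 0L || length(hi) == 0L) next
    s <- (length(lo) * length(hi)) * (mean(lo) - mean(hi))^2
    if (is.na(best_k) || s > best * (1 + 1e-12)) {
      best <- s
      best_k <- k
    }
  }
  r[1] + best_k * width
}

# textbook balanced two-way sums of squares, coded from the definitions
oracle_anova_ss <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  g <- mean(y)
  ss_a <- sum(tapply(y, a, length) * (tapply(y, a, mean) - g)^2)
  ss_b <- sum(tapply(y, b, length) * (tapply(y, b, mean) - g)^2)
  cell_mean <- tapply(y, interaction(a, b), mean)
  cell_n <- tapply(y, interaction(a, b), length)
  a_of_cell <- tapply(as.numeric(a), interaction(a, b), unique)
  b_of_cell <- tapply(as.numeric(b), interaction(a, b), unique)
  am <- tapply(y, a, mean)[a_of_cell]
  bm <- tapply(y, b, mean)[b_of_cell]
  ss_ab <- sum(cell_n * (cell_mean - am - bm + g)^2)
  fitted <- cell_mean[interaction(a, b)]
  ss_res <- sum((y - fitted)^2)
  list(ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab, ss_res = ss_res,
       ss_total = sum((y - g)^2))
}

# BFS flood fill (26-connectivity) over a logical 3D mask
oracle_flood_fill <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  nxt <- 0L
  idx_of <- function(z, y, x) z + dm[1] * ((y - 1) + dm[2] * (x - 1))
  for (x0 in seq_len(dm[3])) for (y0 in seq_len(dm[2])) for (z0 in seq_len(dm[1])) {
    if (!mask[z0, y0, x0] || lab[z0, y0, x0] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(z0, y0, x0))
    lab[z0, y0, x0] <- nxt
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dz == 0 && dy == 0 && dx == 0) next
        z <- v[1] + dz; y <- v[2] + dy; x <- v[3] + dx
        if (z < 1 || z > dm[1] || y < 1 || y > dm[2] ||
            x < 1 || x > dm[3]) next
        if (mask[z, y, x] && lab[z, y, x] == 0L) {
          lab[z, y, x] <- nxt
          queue[[length(queue) + 1]] <- c(z, y, x)
        }
      }
    }
  }
  lab
}

# balanced 2x2 factorial fixture with configurable true effects
balanced_2x2 <- function(effect_a = 0, effect_b = 0, interaction = 0,
                         n = 5, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    d <- expand.grid(rep_id = seq_len(n), age_group = c("4mo", "17mo"),
                     genotype = c("WT", "KO"),
                     stringsAsFactors = FALSE)
    mu <- 10 +
      effect_a * (d$age_group == "17mo") +
      effect_b * (d$genotype == "KO") +
      interaction * (d$age_group == "17mo") * (d$genotype == "KO")
    d$value <- mu + rnorm(nrow(d), sd = sd)
    d
  })
}

# small fast puncta-field preset for unit tests (overrides win)
tiny_field_params <- function(...) {
  args <- list(shape = c(8L, 64L, 64L), n_reference = 20L,
               n_target = 20L, coloc_fraction = 0.5)
  over <- list(...)
  for (nm in names(over)) args[[nm]] <- over[[nm]]
  do.call(puncta_field_params, args)
}

# grouping equality up to label renaming
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(as.integer(factor(a, levels = unique(a))) ==
          as.integer(factor(b, levels = unique(b))))
}
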