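# Independent brute-force oracles. These re-evaluate the geometric and
# physical predicates with plain double loops, deliberately sharing no
# code with the implementation they check.

brute_force_contacts <- function(xyz, roles, sel_a, sel_b, criteria) {
  cr <- criteria
  hpar <- rep(NA_integer_, nrow(xyz))
  heavy_idx <- which(roles$heavy)
  for (h in which(roles$hydrogen)) {
    d <- sqrt(colSums((t(xyz[heavy_idx, , drop = FALSE]) - xyz[h, ])^2))
    if (min(d) <= 1.3) hpar[h] <- heavy_idx[which.min(d)]
  }
  any_h <- any(roles$hydrogen)
  out <- list()
  for (i in sel_a) {
    for (j in sel_b) {
      if (!roles$heavy[i] || !roles$heavy[j]) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      kind <- NULL
      ionic <- (roles$cation[i] && roles$anion[j]) ||
               (roles$anion[i] && roles$cation[j])
      if (ionic && d <= cr@saltbridge_max) {
        kind <- "saltbridge"
      } else {
        hb <- FALSE
        for (pol in 1:2) {
          don <- if (pol == 1) i else j
          acc <- if (pol == 1) j else i
          if (roles$donor[don] && roles$acceptor[acc] &&
              d <= cr@hbond_da_max) {
            if (cr@heavy_atom_fallback || !any_h) {
              hb <- TRUE
            } else {
              for (h in which(hpar == don)) {
                v1 <- xyz[don, ] - xyz[h, ]
                v2 <- xyz[acc, ] - xyz[h, ]
                cosa <- sum(v1 * v2) /
                  sqrt(sum(v1^2) * sum(v2^2))
                if (acos(max(-1, min(1, cosa))) * 180 / pi >=
                    cr@hbond_angle_min) hb <- TRUE
              }
            }
          }
        }
        if (hb) {
          kind <- "hbond"
        } else if (roles$apolar[i] && roles$apolar[j] &&
                   d <= cr@hydrophobic_max) {
          kind <- "hydrophobic"
        } else if (d <= roles$vdw[i] + roles$vdw[j] + cr@vdw_slack) {
          kind <- "vdw"
        }
      }
      if (!is.null(kind))
        out[[length(out) + 1]] <- paste(kind, i, j)
    }
  }
  sort(unlist(out))
}

brute_force_coulomb <- function(xyz, charges, sel_a, sel_b,
                                cutoff = Inf, dielectric = 1) {
  e <- 0
  for (i in sel_a) {
    for (j in sel_b) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (r <= cutoff)
        e <- e + 332.0636 * charges[i] * charges[j] / (dielectric * r)
    }
  }
  e
}

# occurrence-ratio recount straight from raw contact records
brute_force_openbook <- function(table, frame_count) {
  pairs <- unique(table[, c("residue_a", "residue_b")])
  score <- list()
  for (r in seq_len(nrow(pairs))) {
    sel <- table$residue_a == pairs$residue_a[r] &
           table$residue_b == pairs$residue_b[r]
    ratio <- length(unique(table$frame[sel])) / frame_count
    for (res in c(pairs$residue_a[r], pairs$residue_b[r])) {
      score[[res]] <- (if (is.null(score[[res]])) 0 else score[[res]]) +
        ratio
    }
  }
  unlist(score)
}
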