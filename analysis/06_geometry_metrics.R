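# 06: Geometric characterisation of bound ligands on deterministic fixtures:
# per-residue hydrogen-bond count series, and superposition-based RMSD traces
# for four ligand copies with scripted heterogeneous stability (two stay put,
# two drift - the loose-vs-tight binding fingerprint).

source("analysis/00_common.R")

say("hydrogen-bond series on the constructed donor/acceptor fixture")
hb <- make_geometry_fixtures("hbond", seed = cfg$seed)
roles <- attr(hb, "hbond_roles")
ser <- hbond_series(hb, roles$donors, roles$hydrogens, roles$acceptors,
                    path = file.path(results_dir, "hbond_series.tsv"))
say("  bonds per residue at frame 1: %s",
    paste(names(ser)[-1], unlist(ser[1, -1]), sep = "=", collapse = ", "))

say("ligand RMSD series on the four-copy pose fixture (drift 0.2 nm, jitter 0.02)")
lp <- make_geometry_fixtures("ligand_pose", n_frames = 200, drift = 0.2,
                             jitter = 0.02, seed = cfg$seed)
pr <- attr(lp, "pose_roles")
rser <- ligand_rmsd_series(lp, pr$copies, pr$fit)
tsv(rser, "ligand_rmsd.tsv")
mx <- apply(as.matrix(rser[, -1]), 2, max)
say("  max RMSD per copy (nm): %s",
    paste(sprintf("%.2f", mx), collapse = ", "))
say("  stable copies stay near the jitter floor; drifting copies step up -")
say("  the max/min contrast (%.1fx) is the loose-binding signature", max(mx) / min(mx))
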