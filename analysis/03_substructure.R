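# Locate the Hg site: scale the derivative onto the native, synthesize the
# isomorphous and anomalous difference Pattersons, inspect the Harker
# sections, and run the symmetry-minimum site search.

source("analysis/00_common.R")

truth <- study_truth()
st <- prepared_streams(truth)
nm <- merge_patterns(st$native, truth$cell, truth$sg, TRUE)
dm <- merge_patterns(st$derivative, truth$cell, truth$sg, TRUE)

sp <- scale_derivative(nm, dm)
message(sprintf("derivative scaling: k = %.4f, B_rel = %.2f, R_iso = %.3f over %d reflections",
                sp$k, sp$b_rel, sp$r_iso, sp$n_common))

pm_iso <- patterson_map(sp$data[, .(h, k, l)], sp$data$dF_iso^2,
                        truth$cell, truth$sg)
ad <- sp$data[is.finite(dI_ano)]
w_ano <- (ad$dI_ano / pmax(ad$F_PH^2, quantile(ad$F_PH^2, 0.1)))^2
pm_ano <- patterson_map(ad[, .(h, k, l)], w_ano, truth$cell, truth$sg)

# Harker-section values at the true self-vectors (ground truth available
# in the synthetic setting)
site <- as.numeric(truth$heavy_sites[1, c("x", "y", "z")])
secs <- harker_sections(truth$sg)
harker_tbl <- rbindlist(lapply(secs, function(sec) {
  v <- sec$vector_fn(site)
  data.table(section = c("u", "v", "w")[sec$axis], level = sec$level,
             u = round(v[1], 3), v = round(v[2], 3), w = round(v[3], 3),
             iso_sigma = round(sirasfx:::grid_interp(pm_iso, rbind(v)), 2),
             ano_sigma = round(sirasfx:::grid_interp(pm_ano, rbind(v)), 2))
}))
write_result(harker_tbl, "03_harker_true_vectors.tsv")
print(harker_tbl)

loc <- locate_heavy_site(nm, dm, truth)
message(sprintf("top site (%.3f, %.3f, %.3f), score %.2f sigma, %.2f A from the true site (mod origin/hand)",
                loc$site[1], loc$site[2], loc$site[3],
                loc$candidates$score[1], loc$site_error))
write_result(loc$candidates, "03_site_candidates.tsv")
write_pdb_sites("results/03_found_site.pdb", loc$model, truth$cell, truth$sg)

# anomalous difference Fourier with the true native phases: where is the
# anomalous scatterer once phases are known?
plus <- truth$sf_native[branch == 1]
adf <- anomalous_difference_fourier(
  sp, data.table(h = plus$h, k = plus$k, l = plus$l, phi_best = plus$phase),
  truth$cell, truth$sg)
write_result(adf$peaks, "03_anomalous_fourier_peaks.tsv")
message(sprintf("anomalous difference Fourier: top peak %.1f sigma", adf$peaks$height[1]))
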