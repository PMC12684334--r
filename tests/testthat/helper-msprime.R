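# Independent coalescent oracle: the msprime simulator, driven through
# the command-line python interpreter. Returns the site-mode joint AFS
# (unfolded, (n1+1) x (n2+1) counts) for a symmetric IM history in the
# package's units (time in 2*Nref generations, sizes relative to Nref,
# per-lineage migration rate per unit time).

msprime_im_jsfs <- function(n1_dip, n2_dip, n_loci, N1, N2, Na, Ts, m,
                            theta_locus, seed) {
  py <- Sys.which("python")
  if (py == "") stop("python interpreter not found")
  script <- tempfile(fileext = ".py")
  out <- tempfile(fileext = ".txt")
  writeLines(sprintf('
import msprime, numpy as np
Nref = 1000.0
dem = msprime.Demography()
dem.add_population(name="p1", initial_size=%f * Nref)
dem.add_population(name="p2", initial_size=%f * Nref)
dem.add_population(name="anc", initial_size=%f * Nref)
dem.set_symmetric_migration_rate(["p1", "p2"], %f / (2 * Nref))
dem.add_population_split(time=%f * 2 * Nref, derived=["p1", "p2"], ancestral="anc")
dem.add_population_parameters_change(time=%f * 4 * Nref, population="anc", initial_size=Nref)
dem.sort_events()
mu = %f / (4 * Nref)
afs = None
reps = msprime.sim_ancestry(samples={"p1": %d, "p2": %d}, demography=dem,
                            sequence_length=1, discrete_genome=False,
                            num_replicates=%d, random_seed=%d)
rng_seed = %d
for i, ts in enumerate(reps):
    mts = msprime.sim_mutations(ts, rate=mu, discrete_genome=False,
                                random_seed=rng_seed + i + 1)
    s1 = mts.samples(population=0)
    s2 = mts.samples(population=1)
    a = mts.allele_frequency_spectrum(sample_sets=[s1, s2], mode="site",
                                      polarised=True, span_normalise=False)
    afs = a if afs is None else afs + a
np.savetxt(%s, afs)
', N1, N2, Na, m, Ts, Ts, theta_locus, n1_dip, n2_dip, n_loci,
              seed, seed + 10^6, deparse(out)), script)
  status <- system2(py, script, stdout = TRUE, stderr = TRUE)
  if (!file.exists(out))
    stop("msprime oracle failed: ", paste(status, collapse = "\n"))
  as.matrix(read.table(out))
}
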