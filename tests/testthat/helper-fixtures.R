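# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
    if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
    .fixtures[[name]]
}

defaultPhantom <- function() fixture("phantom", function() makeLabelPhantom())

tissueTab <- function() fixture("tissueTab", function() defaultTissueTable())

zeroCV <- function() list(WM = c(MVF = 0, PD = 0, R1 = 0, R2 = 0),
                          GM = c(MVF = 0, PD = 0, R1 = 0, R2 = 0),
                          deepGM = c(MVF = 0, PD = 0, R1 = 0, R2 = 0),
                          CSF = c(MVF = 0, PD = 0, R1 = 0, R2 = 0))

zeroNoise <- function() c(MVF = 0, PD = 0, R1 = 0, R2 = 0)

# spec with no randomness in the maps at all
quietSpec <- function(...) cohortSpec(cv = zeroCV(), noiseSD = zeroNoise(), ...)

# a noise-free subject equal to the tissue table everywhere
quietSubject <- function(seed = 1, group = "atlasHC", ...)
    fixture(paste0("quiet", seed, group), function()
        generateSubject(defaultPhantom(), tissueTab(), quietSpec(...),
                        seed, group = group))

# per-subject ROI means for a default-variability HC cohort of size n,
# cached by (seed, n); subjects are discarded after extraction
cohortMeansFixture <- function(n = 58, seed = 1) {
    fixture(sprintf("cm_%d_%d", n, seed), function() {
        ph <- defaultPhantom(); tt <- tissueTab(); sp <- cohortSpec()
        out <- vector("list", n)
        ages <- numeric(n)
        for (i in seq_len(n)) {
            s <- generateSubject(ph, tt, sp,
                                 qmriAtlas:::deriveSeed(seed,
                                                        paste0("hc", i)),
                                 id = sprintf("HC%03d", i))
            df <- subjectROIMeans(s, ph)
            df$id <- s@id
            out[[i]] <- df
            ages[i] <- s@age
        }
        list(means = do.call(rbind, out),
             manifest = data.frame(id = sprintf("HC%03d", seq_len(n)),
                                   age = ages))
    })
}

# ground-truth table value for an ROI (pair names average both sides)
truthValue <- function(roi, param, tt = tissueTab()) {
    if (roi %in% tt$tissue) return(tt[tt$tissue == roi, param])
    mean(tt[tt$tissue %in% paste0(roi, c("L", "R")), param])
}

# MVF atlas over an n = 58 default-variability cohort without voxel noise
mvfAtlasFixture <- function(seed = 2) {
    fixture(paste0("mvfAtlas", seed), function() {
        ph <- defaultPhantom(); tt <- tissueTab()
        sp <- cohortSpec(noiseSD = zeroNoise())
        vols <- lapply(seq_len(58), function(i)
            subjectMaps(generateSubject(ph, tt, sp,
                qmriAtlas:::deriveSeed(seed, paste0("a", i)),
                id = sprintf("A%03d", i)))$MVF)
        buildAtlas(vols, "MVF", mask = brainMask(ph))
    })
}
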