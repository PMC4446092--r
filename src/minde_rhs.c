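/* Right-hand side of the six-species Min reaction-diffusion system on a 1D
 * axial finite-volume grid, in the form expected by deSolve's compiled-model
 * interface.  The grid and rate constants are staged from R via
 * C_minde_setup() before each integration; deSolve then calls minde_derivs()
 * through its dllname/func mechanism.
 *
 * State layout (cell-major): y[6*i + k], k = 0..5 ->
 *   0 D     cytosolic MinD.ATP monomer   (um^-3)
 *   1 E2    cytosolic MinE dimer         (um^-3)
 *   2 d     membrane MinD monomer        (um^-2)
 *   3 d2    membrane MinD dimer          (um^-2)
 *   4 e2    membrane MinE dimer          (um^-2)
 *   5 d2e2  membrane MinDE heterotetramer(um^-2)
 *
 * With this ordering the Jacobian is banded with half-bandwidth 6 up to the
 * (weak, global) production coupling, which the banded Newton iteration
 * tolerates.
 */

#include <R.h>
#include <Rinternals.h>

static int    mde_n = 0;        /* number of axial cells */
static double mde_rates[9];     /* wdb wedf wdim whydr web wer DD DE Dm */
static double *mde_V   = NULL;  /* cell cytosol volume, um^3            */
static double *mde_A   = NULL;  /* cell lateral membrane area, um^2     */
static double *mde_AoV = NULL;  /* A/V per cell, um^-1                  */
static double *mde_gc  = NULL;  /* n-1 cytosol edge conductance a/dx, um */
static double *mde_gm  = NULL;  /* n-1 membrane edge conductance p/ds    */
static int    *mde_cyl = NULL;  /* 1 if cell lies in the cylinder section */
static double mde_dil  = 0.0;   /* dilution rate growth/L_cyl, s^-1      */
static double mde_tau  = 0.0;   /* production relaxation time; 0 = off   */
static double mde_targD = 0.0;  /* target mean MinD monomers, um^-3      */
static double mde_targE = 0.0;  /* target mean MinE dimers, um^-3        */
static double mde_Vtot = 0.0;

static void mde_free(void)
{
    if (mde_V)   { free(mde_V);   mde_V = NULL; }
    if (mde_A)   { free(mde_A);   mde_A = NULL; }
    if (mde_AoV) { free(mde_AoV); mde_AoV = NULL; }
    if (mde_gc)  { free(mde_gc);  mde_gc = NULL; }
    if (mde_gm)  { free(mde_gm);  mde_gm = NULL; }
    if (mde_cyl) { free(mde_cyl); mde_cyl = NULL; }
    mde_n = 0;
}

/* rates: numeric(9); V, A: numeric(n); gcyt, gmem: numeric(n-1);
 * cyl: integer(n); opts: numeric(5) = dil, tau, targD, targE, Vtot  */
SEXP C_minde_setup(SEXP rates, SEXP V, SEXP A, SEXP gcyt, SEXP gmem,
                   SEXP cyl, SEXP opts)
{
    int n = LENGTH(V);
    if (LENGTH(rates) != 9) error("expected 9 rate constants");
    if (LENGTH(A) != n || LENGTH(cyl) != n)
        error("inconsistent grid array lengths");
    if (LENGTH(gcyt) != n - 1 || LENGTH(gmem) != n - 1)
        error("edge conductance arrays must have length n-1");
    if (LENGTH(opts) != 5) error("expected 5 option values");

    mde_free();
    mde_n   = n;
    mde_V   = (double *) malloc(n * sizeof(double));
    mde_A   = (double *) malloc(n * sizeof(double));
    mde_AoV = (double *) malloc(n * sizeof(double));
    mde_gc  = (double *) malloc((n - 1) * sizeof(double));
    mde_gm  = (double *) malloc((n - 1) * sizeof(double));
    mde_cyl = (int *)    malloc(n * sizeof(int));
    if (!mde_V || !mde_A || !mde_AoV || !mde_gc || !mde_gm || !mde_cyl) {
        mde_free();
        error("allocation failure in minde setup");
    }

    memcpy(mde_rates, REAL(rates), 9 * sizeof(double));
    memcpy(mde_V, REAL(V), n * sizeof(double));
    memcpy(mde_A, REAL(A), n * sizeof(double));
    memcpy(mde_gc, REAL(gcyt), (n - 1) * sizeof(double));
    memcpy(mde_gm, REAL(gmem), (n - 1) * sizeof(double));
    memcpy(mde_cyl, INTEGER(cyl), n * sizeof(int));

    mde_Vtot = 0.0;
    for (int i = 0; i < n; i++) {
        mde_AoV[i] = mde_A[i] / mde_V[i];
        mde_Vtot += mde_V[i];
    }

    double *o = REAL(opts);
    mde_dil = o[0]; mde_tau = o[1]; mde_targD = o[2]; mde_targE = o[3];
    if (o[4] > 0) mde_Vtot = o[4];

    return ScalarInteger(6 * n);
}

/* no-op parameter initialiser required by deSolve's compiled interface */
void minde_initmod(void (*odeparms)(int *, double *))
{
    (void) odeparms;
}

void minde_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    (void) t; (void) yout; (void) ip;
    const int n = mde_n;
    if (*neq != 6 * n) error("state length does not match staged grid");

    const double wdb  = mde_rates[0], wedf = mde_rates[1];
    const double wdim = mde_rates[2], whyd = mde_rates[3];
    const double web  = mde_rates[4], wer  = mde_rates[5];
    const double DD   = mde_rates[6], DE   = mde_rates[7];
    const double Dm   = mde_rates[8];

    /* pointwise reactions + membrane-cytosol exchange */
    for (int i = 0; i < n; i++) {
        const double *s = y + 6 * i;
        double *ds = ydot + 6 * i;
        const double D = s[0], E2 = s[1], d = s[2], d2 = s[3],
                     e2 = s[4], de = s[5];

        const double bindD = wdb * D;          /* um^-2 s^-1 */
        const double dimer = wdim * d * d;
        const double expel = wedf * e2 * d;    /* e2-catalysed monomer release */
        const double tetra = wedf * e2 * d2;
        const double hydro = whyd * de;
        const double bindE = web * E2;
        const double relE  = wer * e2;

        ds[2] = bindD - 2.0 * dimer - expel;           /* d    */
        ds[3] = dimer - tetra;                          /* d2   */
        ds[4] = bindE - relE - tetra + hydro;           /* e2   */
        ds[5] = tetra - hydro;                          /* d2e2 */
        /* surface fluxes, positive = membrane -> cytosol */
        ds[0] = (expel + 2.0 * hydro - bindD) * mde_AoV[i];
        ds[1] = (relE - bindE) * mde_AoV[i];
    }

    /* diffusion: cytosolic species through cross-section, membrane species
     * along the arc with multiplicity-scaled coefficients 1, 1/2, 1/2, 1/4 */
    const double dcoef[6] = { DD, DE, Dm, 0.5 * Dm, 0.5 * Dm, 0.25 * Dm };
    for (int i = 0; i < n - 1; i++) {
        const double gcy = mde_gc[i], gme = mde_gm[i];
        for (int k = 0; k < 6; k++) {
            const double g = (k < 2) ? gcy : gme;
            const double f = dcoef[k] * g * (y[6 * (i + 1) + k] - y[6 * i + k]);
            if (k < 2) {
                ydot[6 * i + k]       += f / mde_V[i];
                ydot[6 * (i + 1) + k] -= f / mde_V[i + 1];
            } else {
                ydot[6 * i + k]       += f / mde_A[i];
                ydot[6 * (i + 1) + k] -= f / mde_A[i + 1];
            }
        }
    }

    /* growing-domain dilution in the cylinder section */
    if (mde_dil > 0.0) {
        for (int i = 0; i < n; i++) {
            if (!mde_cyl[i]) continue;
            for (int k = 0; k < 6; k++)
                ydot[6 * i + k] -= mde_dil * y[6 * i + k];
        }
    }

    /* homogeneous cytosolic production holding cell-mean concentrations */
    if (mde_tau > 0.0) {
        double totD = 0.0, totE = 0.0;
        for (int i = 0; i < n; i++) {
            const double *s = y + 6 * i;
            totD += s[0] * mde_V[i] +
                    (s[2] + 2.0 * s[3] + 2.0 * s[5]) * mde_A[i];
            totE += s[1] * mde_V[i] + (s[4] + s[5]) * mde_A[i];
        }
        const double sD = (mde_targD * mde_Vtot - totD) / (mde_tau * mde_Vtot);
        const double sE = (mde_targE * mde_Vtot - totE) / (mde_tau * mde_Vtot);
        for (int i = 0; i < n; i++) {
            ydot[6 * i]     += sD;
            ydot[6 * i + 1] += sE;
        }
    }
}
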