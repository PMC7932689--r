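/* ARSLIP equations of motion in polar coordinates, for use as a
 * compiled deSolve model.  State y = (r, theta, rdot, thetadot),
 * parameters parms = (ks, ka, R, m, g).  SLIP is the ka = 0 case.
 *
 * Root function flags "falls": leg collapse (r < 0.05 R) or the leg
 * angle leaving (-pi/2, pi/2).
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

static double parms[5];
#define KS parms[0]
#define KA parms[1]
#define RNAT parms[2]
#define MASS parms[3]
#define GRAV parms[4]

void arslip_init(void (*odeparms)(int *, double *))
{
    int n = 5;
    odeparms(&n, parms);
}

void arslip_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double r = y[0], th = y[1], rd = y[2], thd = y[3];
    ydot[0] = rd;
    ydot[1] = thd;
    ydot[2] = r * thd * thd + KS / MASS * (RNAT - r) - GRAV * cos(th);
    ydot[3] = -2.0 * thd * rd / r - KA * th / (MASS * r * r)
              + GRAV / r * sin(th);
}

void arslip_root(int *neq, double *t, double *y, int *ng, double *gout,
                 double *out, int *ip)
{
    gout[0] = y[0] - 0.05 * RNAT;
    gout[1] = M_PI_2 - fabs(y[1]);
}

static const R_CMethodDef cMethods[] = {
    {NULL, NULL, 0}
};

void R_init_arslip(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    /* deSolve looks the model symbols up by name */
    R_useDynamicSymbols(dll, TRUE);
}
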